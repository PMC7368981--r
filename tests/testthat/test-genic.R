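test_that("metagene profile aligns offsets around the CDS start", {
    asm <- tinyAssembly(c(`1A` = 20000))
    ## constant track -> flat profile
    genes <- mkGenes(asm, "1A", 5000, 9000, cds_start = 5200, cds_end = 8800)
    flat <- metageneProfile(asDNSTrack(BinTrack(asm, values = 0.3)), genes)
    expect_equal(nrow(flat), 200L)
    expect_equal(flat$offset, seq(-1000, 990, 10))
    expect_equal(flat$mean, rep(0.3, 200))
    ## impulse 210 bp upstream of the CDS start shows at offset -210
    v <- numeric(2000)
    v[(5200 - 210 - 1) %/% 10 + 1] <- 1
    mg <- metageneProfile(tinyTrack(list(`1A` = v), c(`1A` = 20000)), genes)
    expect_equal(mg$offset[which.max(mg$mean)], -210)
})

test_that("metagene of the reflected genome is identical (strand handling)", {
    fx <- fxSmall()
    dns <- fx$pipe$dns
    genes <- fx$truth$genes
    mg <- metageneProfile(dns, genes)
    ## reflect every chromosome at bin resolution
    asm <- fx$truth$assembly
    L <- chromLengths(asm)
    vals <- lapply(trackValues(dns), rev)
    msk <- lapply(trackMask(dns), rev)
    dnsR <- BinTrack(asm, values = vals, binWidth = binWidth(dns), mask = msk)
    chrom <- as.character(seqnames(genes))
    genesR <- GRanges(chrom,
                      IRanges(L[chrom] - end(genes) + 1,
                              L[chrom] - start(genes) + 1),
                      strand = ifelse(as.character(strand(genes)) == "+",
                                      "-", "+"),
                      seqinfo = asSeqinfo(asm))
    mcols(genesR)$gene_id <- genes$gene_id
    mcols(genesR)$cds_start <- L[chrom] - genes$cds_end + 1
    mcols(genesR)$cds_end <- L[chrom] - genes$cds_start + 1
    mcols(genesR)$confidence <- "HC"
    mgR <- metageneProfile(dnsR, genesR)
    expect_equal(mg$mean, mgR$mean, tolerance = 1e-12)
    expect_equal(mg$count, mgR$count)
})

test_that("region a/b/c/d windows are strand-oriented 500-bp means", {
    asm <- tinyAssembly(c(`1A` = 20000))
    ## values equal to the bin index make window means easy to predict
    v <- seq_len(2000)
    tk <- tinyTrack(list(`1A` = v), c(`1A` = 20000))
    gp <- mkGenes(asm, "1A", 5000, 9000, cds_start = 5001, cds_end = 8800)
    ab <- regionABCD(tk, gp)
    b0 <- (5001 - 1) %/% 10 + 1             # anchor bin
    expect_equal(ab$a, mean(v[(b0 - 100):(b0 - 51)]))
    expect_equal(ab$b, mean(v[(b0 - 50):(b0 - 1)]))
    expect_equal(ab$c, mean(v[b0:(b0 + 49)]))
    expect_equal(ab$d, mean(v[(b0 + 50):(b0 + 99)]))
    ## minus strand flips the window order
    gm <- mkGenes(asm, "1A", 5000, 9000, strand = "-",
                  cds_start = 5200, cds_end = 9000)
    abm <- regionABCD(tk, gm)
    b1 <- (9000 - 1) %/% 10 + 1
    expect_equal(abm$b, mean(v[(b1 + 1):(b1 + 50)]))
    expect_equal(abm$c, mean(v[b1:(b1 - 49)]))
    ## genes too close to the chromosome edge are excluded
    gedge <- mkGenes(asm, "1A", 200, 3000, cds_start = 500, cds_end = 2800)
    expect_equal(nrow(regionABCD(tk, gedge)), 0L)
})

test_that("genic partition windows follow CDS anchors and strand", {
    asm <- tinyAssembly(c(`1A` = 20000))
    v <- seq_len(2000)
    tk <- tinyTrack(list(`1A` = v), c(`1A` = 20000))
    g <- mkGenes(asm, "1A", 4000, 9000, cds_start = 5001, cds_end = 8800)
    gp <- genicPartitionScores(tk, g)
    ## + strand: 500 bp upstream of CDS = [4501, 5000]
    expect_equal(gp$genes$upstream_500, mean(v[451:500]))
    expect_equal(gp$genes$gene_body, mean(v[400:900]))
    gneg <- mkGenes(asm, "1A", 4000, 9000, strand = "-",
                    cds_start = 4200, cds_end = 5000)
    gpn <- genicPartitionScores(tk, gneg)
    ## - strand: 500 bp upstream of CDS = [5001, 5500]
    expect_equal(gpn$genes$upstream_500, mean(v[501:550]))
    ## constant track: every partition equals the constant
    tkc <- asDNSTrack(BinTrack(asm, values = 1.3))
    gpc <- genicPartitionScores(tkc, g)
    expect_equal(unlist(gpc$genes[1, c("gene_body", "upstream_500",
                                       "upstream_2kb", "downstream_2kb")],
                        use.names = FALSE), rep(1.3, 4))
    expect_equal(unique(gpc$intergenic$meanDNS), 1.3)
    ## intergenic space excludes genes +/- 2 kb
    expect_true(all(start(gpc$intergenic) > end(g) + 2000 |
                    end(gpc$intergenic) < start(g) - 2000))
})

test_that("expression-DNS correlation is restricted to expressed genes", {
    set.seed(6)
    dnsv <- rnorm(200)
    scores <- setNames(dnsv, sprintf("g%03d", 1:200))
    tpm <- setNames(exp(dnsv * 2 + rnorm(200, 0, 0.2)), names(scores))
    co <- expressionDnsCorrelation(scores, tpm)
    expect_gt(co$r, 0.8)
    expect_lt(co$p, 1e-6)
    ## permuted labels break the association
    co0 <- expressionDnsCorrelation(scores, setNames(sample(tpm), names(tpm)))
    expect_lt(abs(co0$r), 0.2)
    ## constant DNS is flagged undefined
    expect_warning(
        cc <- expressionDnsCorrelation(setNames(rep(1, 200), names(scores)),
                                       tpm), "constant")
    expect_true(is.na(cc$r))
    ## genes under the tpm floor are dropped
    low <- tpm; low[1:150] <- 0.01
    expect_equal(expressionDnsCorrelation(scores, low)$n, sum(low >= 0.1))
})

test_that("triplet categorization matches the nearest-centroid contract", {
    trip <- data.frame(gene_A = "a1", gene_B = "b1", gene_D = "d1")
    expr <- c(a1 = 10, b1 = 10, d1 = 10)
    expect_equal(categorizeTriplets(trip, expr)$category, "balanced")
    expect_equal(categorizeTriplets(trip, c(a1 = 30, b1 = 1, d1 = 1))$category,
                 "A.dominant")
    expect_equal(categorizeTriplets(trip, c(a1 = 1, b1 = 30, d1 = 30))$category,
                 "A.suppressed")
    expect_equal(categorizeTriplets(trip, c(a1 = 9, b1 = 9, d1 = 0.5))$category,
                 "D.suppressed")
    ## sum below 0.5 tpm is filtered out
    expect_equal(nrow(categorizeTriplets(trip, c(a1 = .1, b1 = .1, d1 = .1))),
                 0L)
    ## missing homoeolog expression skips the triplet with a warning
    expect_warning(out <- categorizeTriplets(trip, c(a1 = 1, b1 = 1)),
                   "missing")
    expect_equal(nrow(out), 0L)
})

test_that("categorization is equivariant under subgenome permutation", {
    set.seed(12)
    n <- 60
    trip <- data.frame(gene_A = sprintf("a%02d", 1:n),
                       gene_B = sprintf("b%02d", 1:n),
                       gene_D = sprintf("d%02d", 1:n))
    eA <- rlnorm(n, 1, 1); eB <- rlnorm(n, 1, 1); eD <- rlnorm(n, 1, 1)
    ex1 <- setNames(c(eA, eB, eD), c(trip$gene_A, trip$gene_B, trip$gene_D))
    ex2 <- setNames(c(eB, eA, eD), c(trip$gene_A, trip$gene_B, trip$gene_D))
    c1 <- categorizeTriplets(trip, ex1)$category
    c2 <- categorizeTriplets(trip, ex2)$category
    swap <- function(x) {
        x <- sub("^A\\.", "tmp.", x)
        x <- sub("^B\\.", "A.", x)
        sub("^tmp\\.", "B.", x)
    }
    expect_equal(swap(c1), c2)
})

test_that("triplet bias tests detect a planted shift and stay calibrated under the null", {
    set.seed(13)
    n <- 100
    mk <- function(shiftA = 0) {
        trip <- data.frame(gene_A = sprintf("a%03d", 1:n),
                           gene_B = sprintf("b%03d", 1:n),
                           gene_D = sprintf("d%03d", 1:n),
                           category = "balanced")
        abcd <- data.frame(
            gene_id = c(trip$gene_A, trip$gene_B, trip$gene_D),
            subgenome = rep(c("A", "B", "D"), each = n),
            a = rnorm(3 * n), b = c(rnorm(n, shiftA), rnorm(2 * n)),
            c = rnorm(3 * n), d = rnorm(3 * n))
        list(trip = trip, abcd = abcd)
    }
    alt <- mk(shiftA = 1)
    tt <- tripletBiasTests(alt$trip, alt$abcd)
    expect_lt(tt$kruskal$p[tt$kruskal$region == "b"], 0.01)
    expect_gt(min(tt$kruskal$p[tt$kruskal$region != "b"]), 0.01)
    pwB <- subset(tt$pairwise, region == "b" & g1 == "A")
    expect_true(all(pwB$p_adj < 0.05))
    ## null p-values are roughly uniform
    set.seed(14)
    ps <- replicate(40, {
        nul <- mk(0)
        min(tripletBiasTests(nul$trip, nul$abcd)$kruskal$p)
    })
    ## min of 4 p-values: P(min < .0025) = 1 percent per draw
    expect_gt(mean(ps > 0.0025), 0.8)
})

test_that("Kruskal-Wallis with two groups matches the Wilcoxon z squared", {
    set.seed(15)
    x <- rnorm(30); y <- rnorm(30, 0.5)
    H <- kruskal.test(list(x, y))$statistic
    w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    n1 <- 30; n2 <- 30; N <- 60
    z <- (w$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(unname(H), unname(z^2), tolerance = 1e-8)
})
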