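## tiny annotated chromosome shared by the context tests
ctxFixture <- function() {
    asm <- tinyAssembly(c(`1A` = 2e5))
    genes <- mkGenes(asm, "1A",
                     start = c(10000, 50000), end = c(13000, 53000),
                     strand = c("+", "-"),
                     cds_start = c(10200, 50200), cds_end = c(12800, 52800))
    tes <- GRanges("1A", IRanges(c(100000, 120000), c(105000, 121000)),
                   seqinfo = asSeqinfo(asm))
    mcols(tes)$family <- c("RLG_famc4", "DTC_famc1")
    mcols(tes)$superfamily <- c("RLG", "DTC")
    mcols(tes)$te_class <- c("1", "2")
    mcols(tes)$is_cereba <- FALSE
    list(asm = asm, genes = genes, tes = tes)
}

mkFp <- function(asm, pos, kind = "MSF") {
    g <- GRanges("1A", IRanges(pos - 50, pos + 49), seqinfo = asSeqinfo(asm))
    mcols(g)$kind <- kind
    g
}

test_that("context assignment follows midpoint precedence rules", {
    fx <- ctxFixture()
    fp <- c(mkFp(fx$asm, 11000),    # inside CDS
            mkFp(fx$asm, 9300),     # 900 bp 5prime of + gene CDS
            mkFp(fx$asm, 53800),    # 1 kb upstream of - strand gene
            mkFp(fx$asm, 49300),    # 0.9 kb downstream of - strand gene
            mkFp(fx$asm, 102000),   # in the Gypsy element
            mkFp(fx$asm, 180000))   # bare intergenic
    ctx <- assignContext(fp, fx$genes, fx$tes)
    expect_equal(ctx$context,
                 c("gene_body", "upstream_2kb", "upstream_2kb",
                   "downstream_2kb", "TE", "unannotated_intergenic"))
    expect_equal(ctx$family[5], "RLG_famc4")
    expect_equal(ctx$te_class[5], "1")
    expect_true(all(is.na(ctx$family[-5])))
})

test_that("context proportions sum to one and resist annotation order", {
    fx <- fxSmall()
    cons <- callConsensus(fx$pipe)
    ctx <- assignContext(cons, fx$truth$genes, fx$truth$tes)
    tab <- table(ctx$context) / nrow(ctx)
    expect_equal(sum(tab), 1)
    perm <- sample(length(fx$truth$genes))
    ctx2 <- assignContext(cons, fx$truth$genes[perm],
                          fx$truth$tes[sample(length(fx$truth$tes))])
    expect_equal(ctx$context, ctx2$context)
})

test_that("a TE inside the genic envelope yields TE only under te-first", {
    fx <- ctxFixture()
    teIn <- GRanges("1A", IRanges(9000, 9600), seqinfo = asSeqinfo(fx$asm))
    mcols(teIn)$family <- "DTT_famc1"
    mcols(teIn)$superfamily <- "DTT"
    mcols(teIn)$te_class <- "2"
    mcols(teIn)$is_cereba <- FALSE
    fp <- mkFp(fx$asm, 9300)
    expect_equal(assignContext(fp, fx$genes, teIn)$context, "upstream_2kb")
    expect_equal(assignContext(fp, fx$genes, teIn,
                               precedence = "te-first")$context, "TE")
})

test_that("context labels are invariant under chromosome reflection", {
    fx <- ctxFixture()
    L <- chromLengths(fx$asm)[["1A"]]
    fp <- c(mkFp(fx$asm, 11000), mkFp(fx$asm, 9300), mkFp(fx$asm, 53800),
            mkFp(fx$asm, 102000))
    refl <- function(gr) {
        out <- GRanges("1A", IRanges(L - end(gr) + 1, L - start(gr) + 1),
                       seqinfo = asSeqinfo(fx$asm))
        mcols(out) <- mcols(gr)
        str <- as.character(strand(gr))
        strand(out) <- ifelse(str == "+", "-", ifelse(str == "-", "+", "*"))
        out
    }
    genesR <- refl(fx$genes)
    mcols(genesR)$cds_start <- L - fx$genes$cds_end + 1
    mcols(genesR)$cds_end <- L - fx$genes$cds_start + 1
    ctx <- assignContext(fp, fx$genes, fx$tes)
    ctxR <- assignContext(refl(fp), genesR, refl(fx$tes))
    expect_equal(ctx$context, ctxR$context)
})

test_that("nearest gene distances: inside zero, edge arithmetic, KDE mode", {
    fx <- ctxFixture()
    fp <- c(mkFp(fx$asm, 11000), mkFp(fx$asm, 9000))
    nd <- nearestGeneDistances(fp, fx$genes)
    expect_equal(nd$distances, c(0, 1000))
    ## mode of a lognormal distance cloud lands near the density peak
    set.seed(5)
    asm <- GenomeAssembly("1A", 1e8)
    gene <- mkGenes(asm, "1A", 1, 1000)
    d <- round(rlnorm(3000, log(1e4), 0.5))
    fps <- GRanges("1A", IRanges(1000 + d, 1000 + d),
                   seqinfo = asSeqinfo(asm))
    mcols(fps)$kind <- "MSF"
    nd2 <- nearestGeneDistances(fps, gene)
    truePeak <- 1e4    # peak of the log-scale density (the estimator's scale)
    expect_lt(abs(nd2$mode - truePeak) / truePeak, 0.10)
})

test_that("fisherEnrichment matches the exact enumeration oracle", {
    ## independent oracle: enumerate the hypergeometric support with choose()
    oracle <- function(tab) {
        m <- tab[1, 1] + tab[1, 2]; n <- tab[2, 1] + tab[2, 2]
        k <- tab[1, 1] + tab[2, 1]
        supp <- max(0, k - n):min(k, m)
        pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
        pobs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) /
            choose(m + n, k)
        sum(pr[pr <= pobs * (1 + 1e-7)])
    }
    expect_equal(fisherEnrichment(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p,
                 34 / 70)
    expect_equal(fisherEnrichment(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))$p,
                 2 / choose(10, 5))
    expect_equal(fisherEnrichment(matrix(5, 2, 2))$p, 1)
    set.seed(8)
    for (i in 1:200) {
        tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
        got <- fisherEnrichment(tab)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
            expect_equal(got$p, 1)
        } else {
            expect_equal(got$p, oracle(tab), tolerance = 1e-9)
        }
    }
    ## sample odds ratio is ad/bc
    expect_equal(fisherEnrichment(matrix(c(6, 2, 3, 4), 2, byrow = TRUE))$odds_ratio,
                 6 * 4 / (2 * 3))
    ## the large-count branch agrees with fisher.test at its boundary
    big <- matrix(c(30000, 50000, 29000, 51000), 2, byrow = TRUE)
    expect_equal(fisherEnrichment(big)$p, fisher.test(big)$p.value,
                 tolerance = 1e-6)
})

test_that("genesNearFootprints credits footprints to every nearby gene", {
    asm <- tinyAssembly(c(`1A` = 50000))
    genes <- mkGenes(asm, "1A", c(10000, 14000), c(11000, 15000))
    fp <- GRanges("1A", IRanges(12400, 12600), seqinfo = asSeqinfo(asm))
    mcols(fp)$kind <- "MSF"
    gn <- genesNearFootprints(fp, genes, radius = 2000)
    expect_equal(unname(gn$counts), c(1, 1))   # both genes within 2 kb
    expect_equal(gn$pctWithFootprint, 100)
    gn0 <- genesNearFootprints(fp[0], genes)
    expect_equal(gn0$pctWithFootprint, 0)
})

test_that("segment summaries: uniform DNS yields equal means", {
    fx <- fxSmall()
    dns <- asDNSTrack(BinTrack(fx$truth$assembly, values = 0.42))
    cons <- callConsensus(fx$pipe)
    ss <- segmentSummaries(dns, cons, fx$truth$segments)
    expect_equal(ss$perSegment$meanDNS, rep(0.42, nrow(ss$perSegment)))
    expect_true(all(c("MSF", "MRF") %in% names(ss$distalTests)))
    expect_true(ss$distalTests$MSF$p <= 1)
})

test_that("state overlap proportions and error handling", {
    fx <- ctxFixture()
    fp <- c(mkFp(fx$asm, 11000), mkFp(fx$asm, 102000, "MRF"))
    states <- GRanges("1A", IRanges(c(1, 100001), c(100000, 200000)),
                      seqinfo = asSeqinfo(fx$asm))
    mcols(states)$label <- c("open", "closed")
    so <- stateOverlap(fp, states)
    pr <- so$proportions
    expect_equal(sum(pr$proportion[pr$kind == "MSF"]), 1)
    expect_equal(pr$proportion[pr$kind == "MSF" & pr$state == "open"], 1)
    expect_equal(pr$proportion[pr$kind == "MRF" & pr$state == "closed"], 1)
    ## empty state set: everything is "none"
    so0 <- stateOverlap(fp, states[0])
    expect_equal(so0$proportions$proportion[so0$proportions$state == "none"],
                 c(1, 1))
    ## overlapping states of different labels are rejected
    bad <- states
    end(bad)[1] <- 150000
    expect_error(stateOverlap(fp, bad), "overlap")
})
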