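test_that("intergenic intervals: gaps, classes and merge rule", {
    asm <- tinyAssembly(c(`1A` = 1e5))
    g <- mkGenes(asm, "1A", c(1, 5001), c(1000, 6000))
    expect_warning(iv <- intergenicIntervals(mkGenes(asm, "1A", 1, 1000,
                                                     id = "solo")),
                   "fewer than 2")
    iv <- intergenicIntervals(g)
    expect_equal(length(iv), 1L)
    expect_equal(c(start(iv), end(iv)), c(1001, 5000))
    expect_equal(iv$length, 4000)
    expect_equal(iv$spacing_class, "lt10kb")
    expect_equal(iv$left_gene, "g001")
    expect_equal(iv$right_gene, "g002")
    ## boundary lengths are closed-left
    g2 <- mkGenes(asm, "1A", c(1, 11001), c(1000, 12000))
    expect_equal(intergenicIntervals(g2)$spacing_class, "10to100kb")
    ## overlapping genes merge into one block, leaving no interval between
    g3 <- mkGenes(asm, "1A", c(1, 51, 9001), c(100, 150, 9500))
    iv3 <- intergenicIntervals(g3)
    expect_equal(length(iv3), 1L)
    expect_equal(start(iv3), 151)
})

test_that("gene blocks + gaps + terminal space tile each chromosome exactly", {
    fx <- fxSmall()
    g <- fx$truth$genes
    iv <- intergenicIntervals(g)
    blocks <- reduce(granges(g), ignore.strand = TRUE)
    for (ch in chromNames(fx$truth$assembly)) {
        b <- blocks[seqnames(blocks) == ch]
        i <- iv[seqnames(iv) == ch]
        terminal <- (min(start(b)) - 1) +
            (chromLengths(fx$truth$assembly)[[ch]] - max(end(b)))
        expect_equal(sum(width(b)) + sum(width(i)) + terminal,
                     unname(chromLengths(fx$truth$assembly)[[ch]]))
    }
})

test_that("decay profiles lay 1-kb windows from both edges to the midpoint", {
    asm <- tinyAssembly(c(`1A` = 1e5))
    g <- mkGenes(asm, "1A", c(1, 5001), c(1000, 6000))
    iv <- intergenicIntervals(g)           # gap [1001, 5000], length 4000
    tk <- asDNSTrack(BinTrack(asm, values = 0.2))
    dc <- decayProfiles(tk, iv)
    expect_equal(sum(dc$series$side == "left"), 2L)   # floor(2000/1000)
    expect_equal(sum(dc$series$side == "right"), 2L)
    expect_equal(dc$series$meanDNS, rep(0.2, 4))
    expect_equal(dc$curves$meanDNS, rep(0.2, 2))
    ## window counts follow floor((length/2)/1000) per side on the fixture
    fx <- fxSmall()
    ivf <- intergenicIntervals(fx$truth$genes)
    dcf <- decayProfiles(fx$pipe$dns, ivf)
    cnt <- table(dcf$series$interval, dcf$series$side)
    nw <- pmax(0, (width(ivf) %/% 2) %/% 1000)
    has <- as.integer(rownames(cnt))
    expect_equal(unname(cnt[, "left"]), unname(nw[has]))
    expect_equal(unname(cnt[, "right"]), unname(nw[has]))
})

test_that("background DNS is the KDE mode with deterministic tie-break", {
    ## mode estimate of N(-0.017, 0.05^2) at n = 1e4: median accuracy over
    ## a few draws is well inside +/- 0.005
    errs <- vapply(16:20, function(s) {
        set.seed(s)
        abs(backgroundDns(rnorm(1e4, -0.017, 0.05)) + 0.017)
    }, numeric(1))
    expect_lt(median(errs), 0.005)
    expect_equal(backgroundDns(rep(0.4, 200)), 0.4)
    expect_true(is.na(backgroundDns(rnorm(50))))
    ## exactly symmetric bimodal input breaks ties to the smaller mode
    y <- c(rnorm(5000, -1, 0.1), rnorm(5000, 1, 0.1))
    y <- c(y, -y)                           # force symmetry
    expect_lt(backgroundDns(y), 0)
})

test_that("spacing-class tests compare short against long intervals", {
    fx <- fxSmall()
    iv <- intergenicIntervals(fx$truth$genes, fx$truth$segments)
    st <- spacingClassTests(fx$pipe$dns, iv, seed = 3)
    expect_true("genome" %in% st$stratum)
    ## short intervals sit in gene-dense distal space: higher DNS
    gw <- st[st$stratum == "genome", ]
    expect_gt(gw$meanShort, gw$meanLong)
    expect_lt(gw$p, 0.05)
})

test_that("TE scores aggregate per element and per family", {
    asm <- tinyAssembly(c(`1A` = 1e5))
    mkTe <- function(s, e, fam) {
        g <- GRanges("1A", IRanges(s, e), seqinfo = asSeqinfo(asm))
        mcols(g)$family <- fam
        mcols(g)$superfamily <- substr(fam, 1, 3)
        mcols(g)$te_class <- "1"
        mcols(g)$is_cereba <- FALSE
        g
    }
    tes <- c(mkTe(1, 1000, "RLG_famc1"), mkTe(2001, 3000, "RLG_famc1"))
    ## constant track: mean c, sd 0
    tc <- teScores(asDNSTrack(BinTrack(asm, values = 0.5)), tes, by = "family")
    expect_equal(tc$mean, 0.5)
    expect_equal(tc$sd, 0)
    ## element means 0.1 and 0.3 -> mean 0.2, sample SD
    v <- numeric(1e4)
    v[1:100] <- 0.1; v[201:300] <- 0.3
    tk <- tinyTrack(list(`1A` = v), c(`1A` = 1e5))
    ts <- teScores(tk, tes, by = "family")
    expect_equal(ts$mean, 0.2)
    expect_equal(ts$sd, sd(c(0.1, 0.3)))
    expect_equal(ts$n, 2L)
    ## order invariance
    ts2 <- teScores(tk, rev(tes), by = "family")
    expect_equal(ts$mean, ts2$mean)
})

test_that("Gypsy-DNS correlation: perfect monotone and degenerate cases", {
    fx <- fxSmall()
    tr <- fx$truth
    ts <- gypsyDnsCorrelation(fx$pipe$dns, tr$tes, window = 2e5, step = 1e5)
    expect_true(all(ts$subgenome %in% c("A", "B", "D")))
    ## planted family effects plus pericentromeric placement give rho < 0
    expect_true(all(ts$rho < 0, na.rm = TRUE))
    ## no Gypsy content -> undefined
    noRlg <- tr$tes[tr$tes$superfamily != "RLG"]
    nr <- gypsyDnsCorrelation(fx$pipe$dns, noRlg, window = 2e5, step = 1e5)
    expect_true(all(is.na(nr$rho)))
})

test_that("Spearman matches an exhaustive rank oracle on tiny inputs", {
    set.seed(17)
    for (i in 1:20) {
        n <- sample(3:8, 1)
        x <- sample(100, n); y <- sample(100, n)
        rho <- cor(x, y, method = "spearman")
        rx <- rank(x); ry <- rank(y)
        oracle <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
        expect_equal(rho, oracle, tolerance = 1e-12)
    }
})

test_that("promoter TE comparison classifies overlap by a single base", {
    asm <- tinyAssembly(c(`1A` = 1e5))
    g <- mkGenes(asm, "1A", 50000, 55000, cds_start = 50200, cds_end = 54800)
    mkTe <- function(s, e) {
        x <- GRanges("1A", IRanges(s, e), seqinfo = asSeqinfo(asm))
        mcols(x)$family <- "RLC_famc1"; mcols(x)$superfamily <- "RLC"
        mcols(x)$te_class <- "1"; mcols(x)$is_cereba <- FALSE
        x
    }
    ## promoter = [48200, 50199]; one TE inside, one 1-bp overlap, one outside
    tes <- c(mkTe(48500, 49000), mkTe(48000, 48200), mkTe(10000, 11000))
    pc <- promoterTeComparison(asDNSTrack(BinTrack(asm, values = 1)), tes, g)
    expect_equal(pc$nWithin, 2L)
    expect_equal(pc$nOutside, 1L)
})

test_that("gene TE-proximity stratifies by class and radius", {
    asm <- tinyAssembly(c(`1A` = 1e5))
    g <- mkGenes(asm, "1A", c(10000, 50000), c(13000, 53000),
                 cds_start = c(10200, 50200), cds_end = c(12800, 52800))
    te <- GRanges("1A", IRanges(13001, 14000), seqinfo = asSeqinfo(asm))
    mcols(te)$family <- "DTC_famc1"; mcols(te)$superfamily <- "DTC"
    mcols(te)$te_class <- "2"; mcols(te)$is_cereba <- FALSE
    expr <- c(g001 = 5, g002 = 5)
    gt <- geneTeProximityEffect(asDNSTrack(BinTrack(asm, values = 1)), expr,
                                te, g)
    any_dns <- gt[gt$te_class == "any" & gt$measure == "gene_body_dns", ]
    expect_equal(any_dns$nNear, 1L)          # adjacent at distance 0
    expect_equal(any_dns$nFar, 1L)
    cls1 <- gt[gt$te_class == "1" & gt$measure == "gene_body_dns", ]
    expect_equal(cls1$nNear, 0L)             # the TE is class 2
    ## with no TEs every gene is far
    gt0 <- geneTeProximityEffect(asDNSTrack(BinTrack(asm, values = 1)), expr,
                                 te[0], g)
    expect_equal(gt0$nNear[1], 0L)
})
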