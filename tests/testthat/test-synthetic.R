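test_that("truth generation is deterministic in (config, seed)", {
    cfg <- syntheticConfig(chroms = c("1A", "1B"), chromLength = 1e6)
    t1 <- generateTruth(cfg, seed = 9)
    t2 <- generateTruth(cfg, seed = 9)
    expect_identical(start(t1$genes), start(t2$genes))
    expect_identical(trackValues(t1$accessibility),
                     trackValues(t2$accessibility))
    expect_identical(start(t1$footprints), start(t2$footprints))
    expect_identical(t1$triplets, t2$triplets)
    t3 <- generateTruth(cfg, seed = 10)
    expect_false(identical(start(t3$genes), start(t1$genes)))
})

test_that("accessibility surface encodes the telomere-centromere gradient", {
    fx <- fxSmall()
    tr <- fx$truth
    a <- asDNSTrack(tr$accessibility)
    segs <- segmentRanges(tr$segments)
    cen <- cenh3Ranges(tr$segments)
    ## intergenic-only comparison, clear of genes, TEs and CENH3
    env <- suppressWarnings(
        reduce(c(granges(tr$genes) + 4000, granges(tr$tes), cen + 2000),
               ignore.strand = TRUE))
    aM <- BinTrack(tr$assembly, values = trackValues(a),
                   mask = maskFromRanges(tr$assembly, env))
    segMean <- function(lab)
        mean(aggregateTrack(aM, segs[segs$label == lab], "mean"), na.rm = TRUE)
    expect_gt(segMean("R1"), segMean("R2a"))
    expect_gt(segMean("R3"), segMean("R2b"))
    expect_gt(segMean("R2a"), segMean("C"))
    ## ablation: disabling the gradient flattens the deep-intergenic
    ## background across segments
    cfg0 <- syntheticConfig(chroms = c("1A", "1B", "1D"), chromLength = 1.5e6,
                            aIntergenicTel = -0.1, aIntergenicCen = -0.1,
                            footprintsPerChrom = 0)
    tr0 <- generateTruth(cfg0, seed = 77)
    env0 <- suppressWarnings(
        reduce(c(granges(tr0$genes) + 8000, granges(tr0$tes),
                 cenh3Ranges(tr0$segments) + 2000), ignore.strand = TRUE))
    a0 <- BinTrack(tr0$assembly, values = trackValues(tr0$accessibility),
                   mask = maskFromRanges(tr0$assembly, env0))
    seg0 <- segmentRanges(tr0$segments)
    sm0 <- vapply(c("R1", "C", "R3"), function(lab)
        mean(aggregateTrack(a0, seg0[seg0$label == lab], "mean"),
             na.rm = TRUE), numeric(1))
    expect_lt(max(sm0) - min(sm0), 0.05)
})

test_that("simulated reads are calibrated: null genome gives near-zero DNS", {
    cfg <- nullConfig(chroms = "1A", chromLength = 1e6)
    tr <- generateTruth(cfg, seed = 33)
    sm <- simulateReads(tr, seed = 33)
    pl <- dnsPipeline(sm, tr$assembly)
    v <- unlist(trackValues(pl$dns))[!unlist(trackMask(pl$dns))]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v)), 3 * se + 1e-3)
})

test_that("doubling depth leaves expected normalized DNS unchanged", {
    fx <- fxSmall()
    tr <- fx$truth
    sm2 <- simulateReads(tr, meanDepth = 2 * tr$config$depthRate, seed = 101)
    pl2 <- dnsPipeline(sm2, tr$assembly)
    fp <- tr$footprints
    msf <- fp[fp$kind == "MSF"]
    a1 <- mean(aggregateTrack(fx$pipe$dns, msf, "mean"))
    a2 <- mean(aggregateTrack(pl2$dns, msf, "mean"))
    expect_lt(abs(a1 - a2) / abs(a1), 0.25)  # same scale, halved noise
})

test_that("expression simulation plants bias categories and the MSF lift", {
    fx <- fxSmall()
    tr <- fx$truth
    ex <- simulateExpression(tr, seed = 101)
    cats <- categorizeTriplets(tr$triplets[, 1:3], ex$expression)
    acc <- mean(cats$category ==
                tr$triplets$category[match(cats$gene_A, tr$triplets$gene_A)])
    expect_gte(acc, 0.95)
    ## 30 percent planted lift for promoter-MSF genes, estimated net of
    ## the per-gene accessibility effect
    bal <- tr$geneCategory[tr$genes$gene_id] == "balanced"
    df <- data.frame(l = log10(ex$expression[tr$genes$gene_id[bal]]),
                     u = tr$genes$u[bal],
                     msf = tr$genes$gene_id[bal] %in% tr$msfGenes)
    lift <- 10^coef(lm(l ~ u + msf, df))[["msfTRUE"]]
    expect_lt(abs(lift - tr$config$msfExpressionLift), 0.10)
    ## gamma = 0 decouples expression from accessibility
    cfg0 <- syntheticConfig(chroms = c("1A", "1B", "1D"),
                            chromLength = 1.5e6, exprGamma = 0)
    tr0 <- generateTruth(cfg0, seed = 101)
    ex0 <- simulateExpression(tr0, seed = 101)
    bal <- tr0$geneCategory[tr0$genes$gene_id] == "balanced"
    co <- cor(tr0$genes$u[bal], log10(ex0$expression[tr0$genes$gene_id[bal]]))
    expect_lt(abs(co), 0.1)
})

test_that("genotype simulation is deterministic and accessibility-linked", {
    fx <- fxSmall()
    g1 <- simulateGenotypesPhenotypes(fx$truth, nIndividuals = 50,
                                      mSnps = 400, seed = 12)
    g2 <- simulateGenotypesPhenotypes(fx$truth, nIndividuals = 50,
                                      mSnps = 400, seed = 12)
    expect_identical(g1$snps$geno, g2$snps$geno)
    expect_identical(g1$phenotypes, g2$phenotypes)
    expect_true(all(g1$truthBin[g1$causal] %in% c(1, 5)))
    ## zero heritability: phenotype variance is pure noise
    g0 <- simulateGenotypesPhenotypes(fx$truth, nIndividuals = 400,
                                      mSnps = 400, h2Open = 0, h2Closed = 0,
                                      seed = 12)
    expect_lt(abs(var(g0$phenotypes$trait1) - 1), 0.25)
})

test_that("generator output files are accepted unchanged by the readers", {
    fx <- fxSmall()
    tr <- fx$truth
    d <- withr::local_tempdir()
    ex <- simulateExpression(tr, seed = 101)
    gp <- simulateGenotypesPhenotypes(tr, nIndividuals = 20, mSnps = 60,
                                      seed = 2)
    writeSyntheticData(tr, d, expression = ex, gp = gp)
    asm <- readChromSizes(file.path(d, "assembly.sizes.tsv"))
    expect_equal(chromLengths(asm), chromLengths(tr$assembly))
    genes <- readGeneModels(file.path(d, "genes.gff3"), asm)
    expect_equal(genes$gene_id, tr$genes$gene_id)
    tes <- readTEAnnotation(file.path(d, "tes.bed"), asm,
                            cerebaFamilies = tr$config$cerebaFamily)
    expect_equal(sum(tes$is_cereba), sum(tr$tes$is_cereba))
    segs <- readSegments(file.path(d, "segments.tsv"), asm)
    expect_equal(start(cenh3Ranges(segs)), start(cenh3Ranges(tr$segments)))
    expr <- readExpression(file.path(d, "expression.tsv"))
    expect_equal(unname(expr), unname(ex$expression))
    trip <- readTriplets(file.path(d, "triplets.tsv"))
    expect_equal(trip$gene_A, tr$triplets$gene_A)
    snps <- readSnpTable(file.path(d, "snps.tsv"))
    expect_equal(unname(snps$geno), unname(gp$snps$geno))
    ph <- readPhenotypes(file.path(d, "phenotypes.tsv"))
    expect_equal(ph$trait1, gp$phenotypes$trait1)
})
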