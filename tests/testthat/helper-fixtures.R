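suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## fixtures are expensive; build once per session and cache
.fx <- new.env(parent = emptyenv())

## small synthetic study: 3 chromosomes x 1.5 Mb, full pipeline
fxSmall <- function() {
    if (is.null(.fx$small)) {
        cfg <- syntheticConfig(chroms = c("1A", "1B", "1D"),
                               chromLength = 1.5e6, footprintsPerChrom = 8)
        tr <- generateTruth(cfg, seed = 101)
        sm <- simulateReads(tr, seed = 101)
        pl <- dnsPipeline(sm, tr$assembly)
        .fx$small <- list(truth = tr, samples = sm, pipe = pl)
    }
    .fx$small
}

## acceptance-scale study: 21 chromosomes (1A..7D) x 2.3 Mb (~48 Mb)
fxBig <- function() {
    if (is.null(.fx$big)) {
        cfg <- syntheticConfig(chroms = paste0(rep(1:7, each = 3),
                                               c("A", "B", "D")),
                               chromLength = 2.3e6, footprintsPerChrom = 5,
                               genesPerMb = 70)
        tr <- generateTruth(cfg, seed = 5)
        sm <- simulateReads(tr, seed = 5)
        pl <- dnsPipeline(sm, tr$assembly)
        .fx$big <- list(truth = tr, samples = sm, pipe = pl)
    }
    .fx$big
}

## matched null genome: flat accessibility, no footprints, no centromere dip
nullConfig <- function(chroms = c("1A", "1B", "1D"), chromLength = 1.5e6) {
    syntheticConfig(chroms = chroms, chromLength = chromLength,
        aIntergenicTel = 0, aIntergenicCen = 0, aGeneBody = 0,
        aPromoter = 0, flankAmp = 0, geneSdAccess = 0, geneWobbleSd = 0,
        aBias = 0, aMsfBump = 0, footprintsPerChrom = 0, aCentromere = 0,
        depthFactor = 1,
        teFamilies = data.frame(family = "RLG_famc1", beta = 0, weight = 1,
                                lenMin = 2000, lenMax = 8000))
}

## per-planted-footprint Jaccard between consensus calls and truth
jaccardToTruth <- function(calls, truth) {
    vapply(seq_along(truth), function(i) {
        same <- calls[calls$kind == truth$kind[i]]
        ov <- subsetByOverlaps(same, truth[i])
        if (!length(ov)) return(0)
        it <- GenomicRanges::intersect(GenomicRanges::reduce(granges(ov)),
                                       granges(truth[i]))
        un <- GenomicRanges::union(granges(ov), granges(truth[i]))
        sum(width(it)) / sum(width(un))
    }, numeric(1))
}

## standard two-replicate consensus calling at the analysis parameters
## used throughout (gap tolerance at half the fragment length)
callConsensus <- function(pipe, maxGapBins = 5L, minLenBins = 5L) {
    f1 <- callFootprints(standardizeTrack(asDNSTrack(pipe$dnsReps[[1]])),
                         maxGapBins = maxGapBins, minLenBins = minLenBins)
    f2 <- callFootprints(standardizeTrack(asDNSTrack(pipe$dnsReps[[2]])),
                         maxGapBins = maxGapBins, minLenBins = minLenBins)
    consensusFootprints(f1, f2, pipe$dns)
}

## per-chromosome bin mask covering a set of ranges (indices clipped)
maskFromRanges <- function(assembly, gr, binWidth = 10) {
    msk <- lapply(chromNames(assembly), function(ch) {
        n <- ceiling(chromLengths(assembly)[[ch]] / binWidth)
        m <- rep(FALSE, n)
        hit <- gr[as.character(seqnames(gr)) == ch]
        for (i in seq_along(hit)) {
            a <- max(1, (start(hit)[i] - 1) %/% binWidth + 1)
            b <- min(n, (end(hit)[i] - 1) %/% binWidth + 1)
            if (a <= b) m[a:b] <- TRUE
        }
        m
    })
    names(msk) <- chromNames(assembly)
    msk
}

## tiny assembly + manual track builder for arithmetic-level tests
tinyAssembly <- function(lengths = c(`1A` = 100)) {
    GenomeAssembly(names(lengths), lengths)
}

tinyTrack <- function(values, lengths = NULL, binWidth = 10, mask = FALSE) {
    if (!is.list(values)) values <- list(`1A` = values)
    if (is.null(lengths))
        lengths <- setNames(vapply(values, length, 1L) * binWidth,
                            names(values))
    BinTrack(GenomeAssembly(names(values), lengths), values = values,
             binWidth = binWidth, mask = mask)
}

## gene model GRanges builder
mkGenes <- function(assembly, chrom, start, end, strand = "+",
                    cds_start = NULL, cds_end = NULL,
                    id = sprintf("g%03d", seq_along(start))) {
    gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                  seqinfo = asSeqinfo(assembly))
    mcols(gr)$gene_id <- id
    mcols(gr)$cds_start <- if (is.null(cds_start)) start else cds_start
    mcols(gr)$cds_end <- if (is.null(cds_end)) end else cds_end
    mcols(gr)$confidence <- "HC"
    gr
}
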