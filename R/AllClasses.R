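#' @import methods
#' @importFrom stats cor coef cov density dhyper fisher.test kruskal.test
#'   lm mad median na.omit optimize p.adjust pnorm qnorm quantile rbinom
#'   rnorm rpois runif sd setNames var wilcox.test nlminb
#' @importFrom utils read.delim write.table head tail
NULL

#' GenomeAssembly: chromosome names, lengths and subgenome labelling
#'
#' Minimal assembly index shared by every stage of the DNS-seq pipeline:
#' an ordered set of chromosome names with lengths, plus a rule mapping a
#' chromosome name to its subgenome (for allopolyploids such as hexaploid
#' wheat, the trailing letter: "1A" -> "A", "chr5D" -> "D").
#'
#' @slot chroms character vector of unique chromosome names (ordered).
#' @slot lengths numeric vector of chromosome lengths in bp, parallel to
#'   \code{chroms}.
#' @slot subgenomeRegex single regex with one capture group applied to a
#'   chromosome name to extract the subgenome label.
#' @export
setClass("GenomeAssembly",
    representation(chroms = "character", lengths = "numeric",
                   subgenomeRegex = "character"),
    validity = function(object) {
        msg <- character()
        if (anyDuplicated(object@chroms))
            msg <- c(msg, "chromosome names must be unique")
        if (length(object@lengths) != length(object@chroms))
            msg <- c(msg, "lengths and chroms must be parallel")
        if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
            msg <- c(msg, "chromosome lengths must be positive and finite")
        if (length(object@subgenomeRegex) != 1L)
            msg <- c(msg, "subgenomeRegex must be a single string")
        if (length(msg)) msg else TRUE
    })

#' BinTrack: fixed-width per-chromosome numeric signal
#'
#' A genomic signal sampled in fixed-width bins (default 10 bp, the DNS-seq
#' resolution). Bin \code{i} of a chromosome covers bases
#' \code{[(i-1)*binWidth + 1, i*binWidth]} (1-based closed); the terminal
#' bin may be shorter. A logical mask marks no-data bins (e.g. bins with
#' zero raw coverage in every digest sample), which are excluded from
#' genome-wide moments and interval aggregation.
#'
#' @slot assembly a \linkS4class{GenomeAssembly}.
#' @slot binWidth integer bin width in bp.
#' @slot values named list (one numeric vector per chromosome).
#' @slot mask named list of logicals, TRUE = masked (no data).
#' @export
setClass("BinTrack",
    representation(assembly = "GenomeAssembly", binWidth = "integer",
                   values = "list", mask = "list"),
    validity = function(object) {
        msg <- character()
        asm <- object@assembly
        nb <- ceiling(asm@lengths / object@binWidth)
        if (!identical(names(object@values), asm@chroms))
            msg <- c(msg, "values must be named by assembly chromosomes")
        else if (!all(lengths(object@values) == nb))
            msg <- c(msg, "per-chromosome value length must be ceiling(length/binWidth)")
        if (!identical(lengths(object@mask), lengths(object@values)))
            msg <- c(msg, "mask must be congruent with values")
        if (length(msg)) msg else TRUE
    })

#' DNSTrack: a BinTrack of differential nuclease sensitivity scores
#'
#' DNS score = per-million normalized light-digest coverage minus
#' per-million normalized heavy-digest coverage per bin; positive scores
#' mark MNase hyper-sensitive (open) chromatin, negative scores
#' hyper-resistant (closed) chromatin. Carries the genome-wide moments
#' (over unmasked bins) used for standardization and footprint calling.
#'
#' @slot provenance character, e.g. replicate ids averaged.
#' @slot genomeMean,genomeSD numeric genome-wide moments (population SD).
#' @export
setClass("DNSTrack", contains = "BinTrack",
    representation(provenance = "character", genomeMean = "numeric",
                   genomeSD = "numeric"))

#' DigestSample: one MNase digest library
#'
#' @slot replicate integer replicate id (1 or 2).
#' @slot digest "light" (10 U/mL MNase) or "heavy" (100 U/mL).
#' @slot reads GRanges of aligned fragment intervals.
#' @slot totalMapped total uniquely mapped reads genome-wide (may exceed
#'   the number of reads supplied when subsetting).
#' @export
setClass("DigestSample",
    representation(replicate = "integer", digest = "character",
                   reads = "GRanges", totalMapped = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!object@digest %in% c("light", "heavy"))
            msg <- c(msg, "digest must be 'light' or 'heavy'")
        if (object@totalMapped < length(object@reads))
            msg <- c(msg, "totalMapped must be >= number of reads supplied")
        if (length(msg)) msg else TRUE
    })

#' ChromosomeSegments: the five-segment chromosome partition
#'
#' Each chromosome is tiled by five ordered segments R1, R2a, C, R2b, R3
#' (distal short arm, interstitial short arm, pericentromeric,
#' interstitial long arm, distal long arm) plus a CENH3 centromere
#' interval contained in C.
#'
#' @slot segments GRanges tiling each chromosome, with mcols column
#'   \code{label} in R1/R2a/C/R2b/R3.
#' @slot cenh3 GRanges, one interval per chromosome.
#' @export
setClass("ChromosomeSegments",
    representation(segments = "GRanges", cenh3 = "GRanges"))
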