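#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges reduce findOverlaps countOverlaps
#'   resize flank shift distance distanceToNearest nearest gaps
#'   follow precede pintersect
#'   makeGRangesFromDataFrame intersect setdiff union
#' @importFrom BiocGenerics sort start end width strand
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomeInfoDb seqnames
#' @importFrom IRanges IRanges ranges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame Rle
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<-
NULL

#' Construct a GenomeAssembly
#'
#' @param chroms character vector of chromosome names.
#' @param lengths numeric vector of chromosome lengths (bp).
#' @param subgenomeRegex regex with one capture group extracting the
#'   subgenome label from a chromosome name. The default captures the
#'   trailing letter, the wheat convention ("1A".."7D").
#' @return a \linkS4class{GenomeAssembly}.
#' @examples
#' asm <- GenomeAssembly(c("1A", "1B", "1D"), c(1e6, 1.2e6, 8e5))
#' subgenomeOf(asm, c("1A", "1D"))
#' @export
GenomeAssembly <- function(chroms, lengths,
                           subgenomeRegex = "([A-Za-z])[0-9]*$") {
    new("GenomeAssembly", chroms = as.character(chroms),
        lengths = setNames(as.numeric(lengths), as.character(chroms)),
        subgenomeRegex = subgenomeRegex)
}

#' @rdname GenomeAssembly
#' @param x,object a GenomeAssembly.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeAssembly
#' @export
setMethod("chromNames", "GenomeAssembly", function(x) x@chroms)

#' @rdname GenomeAssembly
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAssembly
#' @export
setMethod("chromLengths", "GenomeAssembly", function(x) x@lengths)

#' Subgenome label of chromosome names
#'
#' @param assembly a GenomeAssembly.
#' @param chrom character vector of chromosome names.
#' @return character vector of subgenome labels (e.g. "A", "B", "D").
#' @export
subgenomeOf <- function(assembly, chrom) {
    m <- regmatches(chrom, regexec(assembly@subgenomeRegex, chrom))
    vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
           character(1))
}

setMethod("show", "GenomeAssembly", function(object) {
    cat("GenomeAssembly with", length(object@chroms), "chromosomes,",
        sprintf("%.1f Mb total\n", sum(object@lengths) / 1e6))
    n <- min(6L, length(object@chroms))
    for (i in seq_len(n))
        cat(sprintf("  %s  %.0f bp  subgenome %s\n", object@chroms[i],
                    object@lengths[i], subgenomeOf(object, object@chroms[i])))
    if (length(object@chroms) > n) cat("  ...\n")
})

#' Seqinfo view of a GenomeAssembly
#' @param assembly a GenomeAssembly.
#' @return a \code{Seqinfo} for building GRanges bound to the assembly.
#' @export
asSeqinfo <- function(assembly) {
    Seqinfo(seqnames = assembly@chroms,
            seqlengths = as.integer(assembly@lengths))
}

#' Read a chromosome-sizes table (fai-style TSV)
#'
#' Two-column tab-separated file: chromosome name, length. Extra columns
#' (as in .fai) are ignored.
#' @param path file path.
#' @param subgenomeRegex passed to \code{\link{GenomeAssembly}}.
#' @return a GenomeAssembly.
#' @export
readChromSizes <- function(path, subgenomeRegex = "([A-Za-z])[0-9]*$") {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    GenomeAssembly(tab[[1]], as.numeric(tab[[2]]),
                   subgenomeRegex = subgenomeRegex)
}

#' Write chromosome sizes
#' @param assembly a GenomeAssembly.
#' @param path output path.
#' @export
writeChromSizes <- function(assembly, path) {
    write.table(data.frame(chrom = assembly@chroms,
                           length = format(assembly@lengths, scientific = FALSE, trim = TRUE)),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

## number of bins per chromosome at a given bin width
nBinsOf <- function(assembly, binWidth) {
    setNames(as.integer(ceiling(assembly@lengths / binWidth)),
             assembly@chroms)
}

## validate a GRanges (or per-feature vectors) against the assembly
checkWithinAssembly <- function(gr, assembly, what = "interval") {
    chr <- as.character(seqnames(gr))
    bad <- !chr %in% assembly@chroms
    if (any(bad))
        stop("unknown chromosome(s): ", paste(unique(chr[bad]), collapse = ", "))
    len <- assembly@lengths[chr]
    out <- start(gr) < 1L | end(gr) > len
    if (any(out))
        stop(sum(out), " ", what, "(s) outside assembly bounds (first: ",
             chr[which(out)[1]], ":", start(gr)[which(out)[1]], "-",
             end(gr)[which(out)[1]], ")")
    invisible(TRUE)
}

## expand ranges by pad bp on both sides, clipped at chromosome bounds
expandClip <- function(gr, pad) {
    len <- seqlengths(seqinfo(gr))[as.character(seqnames(gr))]
    out <- GRanges(seqnames(gr),
                   IRanges(pmax(start(gr) - pad, 1),
                           pmin(end(gr) + pad, len)),
                   seqinfo = seqinfo(gr))
    mcols(out) <- mcols(gr)
    out
}

## bind a GRanges to the assembly's seqinfo (keeps coordinates untouched)
bindToAssembly <- function(gr, assembly) {
    checkWithinAssembly(gr, assembly)
    si <- asSeqinfo(assembly)
    out <- GRanges(as.character(seqnames(gr)),
                   IRanges(start(gr), end(gr)),
                   strand = strand(gr), seqinfo = si)
    mcols(out) <- mcols(gr)
    out
}
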