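## spacing class from interval length (bp); boundaries closed-left
spacingClassOf <- function(len) {
    cut(len, breaks = c(0, 1e4, 1e5, 1e6, Inf), right = FALSE,
        labels = c("lt10kb", "10to100kb", "100kbto1Mb", "gt1Mb"))
}

#' Intergenic intervals between adjacent gene blocks
#'
#' Overlapping gene models are first merged into occupied blocks; one
#' interval is emitted per adjacent block pair (chromosome-terminal gaps
#' are excluded). Spacing classes: < 10 kb, 10-100 kb, 100 kb - 1 Mb,
#' >= 1 Mb (closed-left boundaries).
#'
#' @param genes GRanges of gene models.
#' @param segments optional \linkS4class{ChromosomeSegments}; when given,
#'   each interval carries the segment label of its midpoint.
#' @return GRanges with mcols \code{length}, \code{spacing_class},
#'   \code{left_gene}, \code{right_gene} and optionally \code{segment}.
#' @export
intergenicIntervals <- function(genes, segments = NULL) {
    blocks <- reduce(granges(genes), ignore.strand = TRUE)
    out <- list()
    for (ch in unique(as.character(seqnames(blocks)))) {
        b <- blocks[seqnames(blocks) == ch]
        b <- b[order(start(b))]
        if (length(b) < 2) {
            warning("chromosome ", ch, ": fewer than 2 gene blocks, no intervals")
            next
        }
        s <- end(b)[-length(b)] + 1
        e <- start(b)[-1] - 1
        keep <- e >= s
        gr <- GRanges(ch, IRanges(s[keep], e[keep]),
                      seqinfo = seqinfo(blocks))
        ## representative flanking gene ids
        gidL <- follow(gr, granges(genes), ignore.strand = TRUE)
        gidR <- precede(gr, granges(genes), ignore.strand = TRUE)
        mcols(gr)$left_gene <- genes$gene_id[gidL]
        mcols(gr)$right_gene <- genes$gene_id[gidR]
        out[[ch]] <- gr
    }
    if (!length(out)) return(GRanges())
    gr <- do.call(c, unname(out))
    mcols(gr)$length <- width(gr)
    mcols(gr)$spacing_class <- as.character(spacingClassOf(width(gr)))
    if (!is.null(segments)) {
        segs <- segmentRanges(segments)
        hit <- findOverlaps(midpoints(gr), segs, select = "first")
        mcols(gr)$segment <- segs$label[hit]
    }
    gr
}

#' DNS decay profiles toward intergenic midpoints
#'
#' For each intergenic interval, mean DNS in consecutive 1-kb windows
#' laid from each flanking gene edge inward until the midpoint
#' (floor((length/2)/1000) full windows per side); the two sides
#' contribute separate decay series. The per-class curve is the mean over
#' all series at each window index.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param intervals GRanges from \code{\link{intergenicIntervals}}.
#' @param windowBp decay window size (default 1000).
#' @return list: \code{series} data.frame (interval, side, windowIndex,
#'   meanDNS, spacing_class), \code{curves} data.frame (spacing_class,
#'   windowIndex, meanDNS, n).
#' @export
decayProfiles <- function(dns, intervals, windowBp = 1000) {
    if (!length(intervals))
        return(list(series = NULL, curves = NULL))
    nw <- pmax(0, (width(intervals) %/% 2) %/% windowBp)
    rows <- list()
    for (side in c("left", "right")) {
        idx <- rep(seq_along(intervals), nw)
        k <- unlist(lapply(nw, seq_len), use.names = FALSE)
        if (!length(idx)) next
        if (side == "left") {
            s <- start(intervals)[idx] + (k - 1) * windowBp
            e <- s + windowBp - 1
        } else {
            e <- end(intervals)[idx] - (k - 1) * windowBp
            s <- e - windowBp + 1
        }
        wgr <- GRanges(seqnames(intervals)[idx], IRanges(s, e),
                       seqinfo = seqinfo(intervals))
        rows[[side]] <- data.frame(
            interval = idx, side = side, windowIndex = k,
            meanDNS = aggregateTrack(dns, wgr, "mean"),
            spacing_class = intervals$spacing_class[idx])
    }
    series <- do.call(rbind, rows)
    rownames(series) <- NULL
    agg <- stats::aggregate(meanDNS ~ spacing_class + windowIndex,
                            data = series, FUN = mean, na.rm = TRUE)
    cnt <- stats::aggregate(meanDNS ~ spacing_class + windowIndex,
                            data = series, FUN = function(x) sum(is.finite(x)))
    agg$n <- cnt$meanDNS
    list(series = series, curves = agg[order(agg$spacing_class,
                                             agg$windowIndex), ])
}

#' Background DNS score per spacing class
#'
#' The mode (peak of a Gaussian KDE, Silverman bandwidth) of the pooled
#' 1-kb-window DNS distribution of a spacing class: the plateau
#' accessibility far from genes. Ties between equal-density modes break
#' to the smaller value.
#'
#' @param series data.frame from \code{\link{decayProfiles}} (element
#'   \code{series}), or a numeric vector of window values.
#' @param class spacing class to pool (ignored for a numeric vector).
#' @param minValues minimum pooled values (default 100).
#' @return the background DNS score (NA if too few values).
#' @export
backgroundDns <- function(series, class = NULL, minValues = 100) {
    x <- if (is.numeric(series)) series
         else series$meanDNS[series$spacing_class == class]
    x <- x[is.finite(x)]
    if (length(x) < minValues) return(NA_real_)
    if (length(unique(x)) == 1L) return(x[1])
    den <- density(x)
    peak <- den$x[den$y >= max(den$y) - 1e-12]
    min(peak)
}

#' Compare interval DNS between spacing classes, stratified by segment
#'
#' Mann-Whitney test of per-interval mean DNS between short (< 100 kb)
#' and long (>= 100 kb) intergenic intervals, genome-wide and within the
#' distal (R1 + R3) and pericentromeric (C) strata, on random equal-size
#' subsamples of the two classes.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param intervals GRanges from \code{\link{intergenicIntervals}} (with
#'   \code{segment} labels for the stratified tests).
#' @param seed RNG seed for the equal-size subsampling.
#' @return data.frame (stratum, nPerClass, meanShort, meanLong, W, p).
#' @export
spacingClassTests <- function(dns, intervals, seed = 1) {
    mv <- aggregateTrack(dns, intervals, "mean")
    short <- intervals$spacing_class %in% c("lt10kb", "10to100kb")
    strata <- list(genome = rep(TRUE, length(intervals)))
    if (!is.null(intervals$segment)) {
        strata$distal <- intervals$segment %in% c("R1", "R3")
        strata$pericentromeric <- intervals$segment == "C"
    }
    set.seed(seed)
    rows <- list()
    for (st in names(strata)) {
        inSt <- strata[[st]] & is.finite(mv)
        xs <- mv[inSt & short]
        xl <- mv[inSt & !short]
        n <- min(length(xs), length(xl))
        if (n < 2) next
        xs <- sample(xs, n)
        xl <- sample(xl, n)
        if (all(xs == xl)) {
            rows[[st]] <- data.frame(stratum = st, nPerClass = n,
                                     meanShort = mean(xs), meanLong = mean(xl),
                                     W = NA_real_, p = 1)
            next
        }
        wt <- wilcox.test(xs, xl, exact = FALSE)
        rows[[st]] <- data.frame(stratum = st, nPerClass = n,
                                 meanShort = mean(xs), meanLong = mean(xl),
                                 W = unname(wt$statistic), p = wt$p.value)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
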