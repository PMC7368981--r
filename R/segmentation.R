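#' Standardize a DNS track
#'
#' z = (value - genome mean) / genome SD on unmasked bins (masked bins are
#' set to 0 and stay masked). Moments are the track's own genome-wide
#' mean and population SD over unmasked bins.
#'
#' @param dns a \linkS4class{DNSTrack} (or BinTrack, promoted first).
#' @return a BinTrack of z-scores.
#' @export
standardizeTrack <- function(dns) {
    dns <- asDNSTrack(dns)
    if (!is.finite(dns@genomeSD) || dns@genomeSD <= 0)
        stop("constant track: genome SD is zero, cannot standardize")
    mu <- dns@genomeMean; sdv <- dns@genomeSD
    vals <- mapply(function(v, m) {
        z <- (v - mu) / sdv
        z[m] <- 0
        z
    }, dns@values, dns@mask, SIMPLIFY = FALSE)
    new("BinTrack", assembly = dns@assembly, binWidth = dns@binWidth,
        values = vals, mask = dns@mask)
}

## maximal candidate runs for one sign, with gap merging.
## state: +1/-1/0 per bin; gap bins may be bridged when the raw z keeps
## the run's sign and the gap is <= maxGapBins.
signRuns <- function(z, state, sign, maxGapBins) {
    r <- rle(state == sign)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    if (!length(cand)) return(matrix(integer(0), ncol = 2))
    s <- starts[cand]
    e <- ends[cand]
    if (maxGapBins > 0L && length(s) > 1L) {
        ## bridge a gap when it is short enough and every gap bin keeps
        ## the run's sign; counts via prefix sums of the sign indicator
        P <- cumsum(c(0L, as.integer(sign * z > 0)))
        k <- length(s)
        gapLen <- s[-1] - e[-k] - 1L
        sameSign <- (P[s[-1]] - P[e[-k] + 1L]) == gapLen
        join <- gapLen <= maxGapBins & sameSign
        grp <- cumsum(c(TRUE, !join))
        s <- as.integer(tapply(s, grp, min))
        e <- as.integer(tapply(e, grp, max))
    }
    cbind(s, e)
}

#' Call MSF/MRF footprints from a standardized track
#'
#' Maximal runs of consecutive bins with z >= cutoff become MNase
#' hyper-sensitive footprints (MSF); runs with z <= -cutoff become
#' hyper-resistant footprints (MRF). Runs separated by at most
#' \code{maxGapBins} sub-threshold bins of same-sign z are merged; a
#' merged segment is retained only if its mean |z| still exceeds the
#' cutoff, and segments shorter than \code{minLenBins} are dropped. The
#' default cutoff of 1.5 genome-wide SD is the biological significance
#' threshold of the DNS-seq design.
#'
#' @param z BinTrack of z-scores (see \code{\link{standardizeTrack}}).
#' @param cutoff positive z threshold (default 1.5).
#' @param maxGapBins merge gap in bins (default 0).
#' @param minLenBins minimum segment length in bins (default 1).
#' @param dns optional DNS BinTrack used to fill \code{mean_dns}.
#' @param replicate replicate label stored in \code{support}.
#' @return GRanges with mcols \code{kind} (MSF/MRF), \code{mean_z},
#'   \code{mean_dns}, \code{support}.
#' @export
callFootprints <- function(z, cutoff = 1.5, maxGapBins = 0L, minLenBins = 1L,
                           dns = NULL, replicate = "1") {
    stopifnot(cutoff > 0)
    asm <- z@assembly
    w <- z@binWidth
    res <- list()
    for (ch in asm@chroms) {
        zv <- z@values[[ch]]
        m <- z@mask[[ch]]
        state <- integer(length(zv))
        state[!m & zv >= cutoff] <- 1L
        state[!m & zv <= -cutoff] <- -1L
        Zc <- cumsum(c(0, zv))
        for (sgn in c(1L, -1L)) {
            segs <- signRuns(zv, state, sgn, as.integer(maxGapBins))
            if (!nrow(segs)) next
            len <- segs[, 2] - segs[, 1] + 1L
            mz <- (Zc[segs[, 2] + 1L] - Zc[segs[, 1]]) / len
            keep <- len >= minLenBins & abs(mz) >= cutoff
            if (!any(keep)) next
            segs <- segs[keep, , drop = FALSE]
            res[[length(res) + 1L]] <- data.frame(
                chrom = ch,
                start = (segs[, 1] - 1) * w + 1,
                end = pmin(segs[, 2] * w, asm@lengths[[ch]]),
                kind = if (sgn > 0) "MSF" else "MRF",
                mean_z = mz[keep])
        }
    }
    if (!length(res)) {
        out <- GRanges(seqinfo = asSeqinfo(asm))
        mcols(out)$kind <- character(0)
        mcols(out)$mean_z <- numeric(0)
        mcols(out)$mean_dns <- numeric(0)
        mcols(out)$support <- character(0)
        return(out)
    }
    tab <- do.call(rbind, res)
    out <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                   seqinfo = asSeqinfo(asm))
    mcols(out)$kind <- tab$kind
    mcols(out)$mean_z <- tab$mean_z
    mcols(out)$mean_dns <- if (is.null(dns)) NA_real_
        else aggregateTrack(dns, out, "mean")
    mcols(out)$support <- replicate
    sort(out, ignore.strand = TRUE)
}

#' Two-replicate consensus footprints
#'
#' A locus is retained only where both replicates called the same
#' footprint kind ("surpass the cutoff in both replicates"): same-kind
#' intervals are coordinate-intersected (or unioned with
#' \code{mode = "union"}), and mean DNS / mean z are recomputed on the
#' resulting intervals from the replicate-averaged DNS track.
#'
#' @param rep1,rep2 GRanges from \code{\link{callFootprints}}.
#' @param dnsAvg replicate-averaged \linkS4class{DNSTrack}.
#' @param mode "intersect" (default) or "union".
#' @return GRanges with mcols kind, mean_dns, mean_z, support.
#' @export
consensusFootprints <- function(rep1, rep2, dnsAvg,
                                mode = c("intersect", "union")) {
    mode <- match.arg(mode)
    zAvg <- standardizeTrack(dnsAvg)
    out <- list()
    for (k in c("MSF", "MRF")) {
        a <- rep1[rep1$kind == k]
        b <- rep2[rep2$kind == k]
        g <- if (mode == "intersect") intersect(granges(a), granges(b))
             else reduce(union(granges(a), granges(b)))
        if (!length(g)) next
        mcols(g)$kind <- k
        out[[k]] <- g
    }
    if (!length(out)) {
        g <- GRanges(seqinfo = asSeqinfo(dnsAvg@assembly))
        mcols(g)$kind <- character(0)
        mcols(g)$mean_dns <- numeric(0)
        mcols(g)$mean_z <- numeric(0)
        mcols(g)$support <- character(0)
        return(g)
    }
    g <- sort(do.call(c, unname(out)), ignore.strand = TRUE)
    mcols(g)$mean_dns <- aggregateTrack(dnsAvg, g, "mean")
    mcols(g)$mean_z <- aggregateTrack(zAvg, g, "mean")
    mcols(g)$support <- "1,2"
    g
}

#' Footprint totals by kind, subgenome and chromosome segment
#'
#' @param footprints GRanges with mcol \code{kind}.
#' @param assembly a GenomeAssembly.
#' @param segments optional \linkS4class{ChromosomeSegments}.
#' @return list of data.frames: \code{byKind} (n, bp, Mb, pctGenome),
#'   \code{bySubgenome}, and (when segments are given) \code{bySegment}.
#' @export
footprintSummary <- function(footprints, assembly, segments = NULL) {
    gsize <- sum(assembly@lengths)
    kinds <- c("MSF", "MRF")
    byKind <- do.call(rbind, lapply(kinds, function(k) {
        f <- footprints[footprints$kind == k]
        data.frame(kind = k, n = length(f), bp = sum(width(f)),
                   Mb = sum(width(f)) / 1e6,
                   pctGenome = 100 * sum(width(f)) / gsize)
    }))
    sg <- subgenomeOf(assembly, as.character(seqnames(footprints)))
    bySub <- do.call(rbind, lapply(kinds, function(k) {
        sel <- footprints$kind == k
        if (!any(sel)) return(NULL)
        agg <- tapply(width(footprints)[sel], sg[sel], sum)
        data.frame(kind = k, subgenome = names(agg), bp = as.numeric(agg))
    }))
    out <- list(byKind = byKind, bySubgenome = bySub)
    if (!is.null(segments)) {
        segs <- segmentRanges(segments)
        rows <- list()
        for (k in kinds) {
            f <- footprints[footprints$kind == k]
            for (lab in c("R1", "R2a", "C", "R2b", "R3")) {
                s <- segs[segs$label == lab]
                ov <- intersect(granges(f), granges(s))
                rows[[paste(k, lab)]] <- data.frame(
                    kind = k, segment = lab, bp = sum(width(ov)),
                    segmentBp = sum(width(s)))
            }
        }
        out$bySegment <- do.call(rbind, rows)
        rownames(out$bySegment) <- NULL
    }
    out
}
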