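#' Cereba TE coverage density in windows
#'
#' Per tiling window, the fraction of bp covered by Cereba-flagged TEs
#' (overlaps counted once: coverage, not sum).
#'
#' @param tes GRanges from \code{\link{readTEAnnotation}} with
#'   \code{is_cereba} flags.
#' @param assembly a GenomeAssembly.
#' @param window window size in bp (default 1 Mb).
#' @return a BinTrack at window resolution.
#' @export
cerebaDensity <- function(tes, assembly, window = 1e6) {
    cer <- reduce(granges(tes[tes$is_cereba]), ignore.strand = TRUE)
    if (!length(cer)) warning("no Cereba-flagged TEs: density is all zero")
    nb <- nBinsOf(assembly, window)
    vals <- lapply(assembly@chroms, function(ch) numeric(nb[[ch]]))
    names(vals) <- assembly@chroms
    if (length(cer)) {
        win <- windowTiles(assembly, window)
        ov <- findOverlaps(win, cer)
        bp <- width(pintersect(win[queryHits(ov)], cer[subjectHits(ov)]))
        agg <- tapply(bp, queryHits(ov), sum)
        dens <- numeric(length(win))
        dens[as.integer(names(agg))] <- as.numeric(agg) / width(win)[as.integer(names(agg))]
        chr <- as.character(seqnames(win))
        for (ch in unique(chr)) vals[[ch]] <- dens[chr == ch]
    }
    BinTrack(assembly, values = vals, binWidth = window)
}

## tiling windows as GRanges (ordered per chromosome)
windowTiles <- function(assembly, window) {
    res <- lapply(assembly@chroms, function(ch) {
        len <- assembly@lengths[[ch]]
        s <- seq(1, len, by = window)
        GRanges(ch, IRanges(s, pmin(s + window - 1, len)),
                seqinfo = asSeqinfo(assembly))
    })
    do.call(c, res)
}

#' Total digest read-depth track at window resolution
#'
#' Window mean of (light + heavy) normalized coverage; the centromere
#' shows a dip because both digests recover centromeric chromatin poorly.
#'
#' @param light,heavy congruent normalized BinTracks.
#' @param window window size in bp (default 1 Mb).
#' @return a BinTrack at window resolution.
#' @export
depthTrack <- function(light, heavy, window = 1e6) {
    tot <- trackMap2(light, heavy, `+`, mask = "and")
    win <- windowSummary(tot, window)
    asm <- light@assembly
    nb <- nBinsOf(asm, window)
    chr <- as.character(seqnames(win))
    vals <- lapply(asm@chroms, function(ch) {
        v <- win$mean[chr == ch]
        length(v) <- nb[[ch]]
        v[is.na(v)] <- 0
        v
    })
    names(vals) <- asm@chroms
    BinTrack(asm, values = vals, binWidth = as.integer(window))
}

## centered running mean over k window-bins
runningMean <- function(v, k) {
    if (k <= 1) return(v)
    cs <- cumsum(c(0, v))
    n <- length(v)
    h <- k %/% 2
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Predict centromere positions from the DNS / Cereba / depth signature
#'
#' Candidate regions are maximal runs of windows whose Cereba density
#' reaches the \code{densityQuantile} of that chromosome's nonzero
#' densities; the predicted point is the center of the window maximizing
#' the smoothed DNS within the candidates (the DNS peak, not the coverage
#' minimum, is the primary locator). Ties within 1 percent of the best
#' smoothed DNS resolve to the lower read depth, then to the smaller
#' coordinate. Without any Cereba candidate the global smoothed-DNS
#' argmax is reported with a low-confidence flag.
#'
#' @param dns window-resolution DNS BinTrack (e.g. from
#'   \code{\link{windowSummary}} means repacked by \code{\link{depthTrack}}
#'   conventions) or any BinTrack whose binWidth equals the analysis
#'   window.
#' @param cereba BinTrack from \code{\link{cerebaDensity}}.
#' @param depth BinTrack from \code{\link{depthTrack}}.
#' @param smoothing smoothing span in bp (default 1 Mb = no smoothing at
#'   1-Mb windows).
#' @param densityQuantile quantile of nonzero Cereba densities defining
#'   candidates (default 0.90).
#' @param cenh3 optional GRanges of CENH3 intervals for validation.
#' @return data.frame with one row per chromosome: predicted point,
#'   candidate regions, diagnostics, low-confidence flag, and (when
#'   \code{cenh3} is given) whether the point falls inside CENH3.
#' @export
predictCentromere <- function(dns, cereba, depth, smoothing = NULL,
                              densityQuantile = 0.90, cenh3 = NULL) {
    stopIfNotCongruent(dns, cereba)
    stopIfNotCongruent(dns, depth)
    w <- dns@binWidth
    k <- if (is.null(smoothing)) 1L else max(1L, as.integer(round(smoothing / w)))
    asm <- dns@assembly
    rows <- list()
    cands <- list()
    for (ch in asm@chroms) {
        sdns <- runningMean(dns@values[[ch]], k)
        cd <- cereba@values[[ch]]
        dp <- depth@values[[ch]]
        nz <- cd[cd > 0]
        lowConf <- FALSE
        if (length(nz)) {
            thr <- quantile(nz, densityQuantile, names = FALSE)
            inCand <- cd >= thr
        } else inCand <- rep(FALSE, length(cd))
        if (any(inCand)) {
            r <- rle(inCand)
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            ci <- which(r$values)
            regs <- cbind(starts[ci], ends[ci])
            pool <- which(inCand)
        } else {
            lowConf <- TRUE
            regs <- matrix(c(1L, length(cd)), 1)
            pool <- seq_along(cd)
        }
        best <- max(sdns[pool])
        near <- pool[sdns[pool] >= best - 0.01 * abs(best)]
        if (length(near) > 1) near <- near[order(dp[near], near)][1]
        pt <- (near - 1) * w + min(w, asm@lengths[[ch]] - (near - 1) * w) / 2
        hit <- NA
        if (!is.null(cenh3)) {
            cen <- cenh3[as.character(seqnames(cenh3)) == ch]
            if (length(cen))
                hit <- any(pt >= start(cen) & pt <= end(cen))
        }
        rows[[ch]] <- data.frame(
            chrom = ch, predicted_point = pt, n_candidates = nrow(regs),
            low_confidence = lowConf, peak_dns = best,
            depth_at_peak = dp[near], cereba_at_peak = cd[near],
            in_cenh3 = hit)
        cands[[ch]] <- GRanges(ch, IRanges((regs[, 1] - 1) * w + 1,
                                           pmin(regs[, 2] * w,
                                                asm@lengths[[ch]])),
                               seqinfo = asSeqinfo(asm))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "candidates") <- cands
    out
}

#' Window-resolution DNS track
#'
#' Repackage a 10-bp DNS track as a window-resolution BinTrack (window
#' mean per bin), the form consumed by \code{\link{predictCentromere}}.
#'
#' @param dns a BinTrack.
#' @param window window size in bp (default 1 Mb).
#' @return a BinTrack with binWidth = window.
#' @export
windowTrack <- function(dns, window = 1e6) {
    win <- windowSummary(dns, window)
    asm <- dns@assembly
    nb <- nBinsOf(asm, window)
    chr <- as.character(seqnames(win))
    vals <- lapply(asm@chroms, function(ch) {
        v <- win$mean[chr == ch]
        length(v) <- nb[[ch]]
        v[is.na(v)] <- 0
        v
    })
    names(vals) <- asm@chroms
    BinTrack(asm, values = vals, binWidth = as.integer(window))
}
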