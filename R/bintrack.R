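#' Construct a BinTrack
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param values named list of per-chromosome numeric vectors, or a single
#'   value recycled genome-wide (default 0).
#' @param binWidth bin width in bp (default 10, the DNS-seq resolution).
#' @param mask named list of per-chromosome logicals (TRUE = no-data), or
#'   a single logical recycled (default FALSE).
#' @return a \linkS4class{BinTrack}.
#' @export
BinTrack <- function(assembly, values = 0, binWidth = 10L, mask = FALSE) {
    binWidth <- as.integer(binWidth)
    nb <- nBinsOf(assembly, binWidth)
    if (!is.list(values))
        values <- lapply(nb, function(n) rep(as.numeric(values), length.out = n))
    if (!is.list(mask))
        mask <- lapply(nb, function(n) rep(as.logical(mask), length.out = n))
    values <- lapply(values, as.numeric)
    mask <- lapply(mask, as.logical)
    names(values) <- names(mask) <- assembly@chroms
    new("BinTrack", assembly = assembly, binWidth = binWidth,
        values = values, mask = mask)
}

#' @rdname BinTrack
#' @param x a BinTrack.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname BinTrack
#' @export
setMethod("binWidth", "BinTrack", function(x) x@binWidth)

#' @rdname BinTrack
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname BinTrack
#' @export
setMethod("trackValues", "BinTrack", function(x) x@values)

#' @rdname BinTrack
#' @export
setGeneric("trackMask", function(x) standardGeneric("trackMask"))
#' @rdname BinTrack
#' @export
setMethod("trackMask", "BinTrack", function(x) x@mask)

#' @rdname BinTrack
#' @export
setGeneric("trackAssembly", function(x) standardGeneric("trackAssembly"))
#' @rdname BinTrack
#' @export
setMethod("trackAssembly", "BinTrack", function(x) x@assembly)

setMethod("show", "BinTrack", function(object) {
    v <- unlist(object@values, use.names = FALSE)
    m <- unlist(object@mask, use.names = FALSE)
    cat(class(object), "with", length(object@values), "chromosomes,",
        length(v), "bins of", object@binWidth, "bp\n")
    cat(sprintf("  unmasked bins: %d (%.1f%%); value range [%.4g, %.4g]\n",
                sum(!m), 100 * mean(!m),
                suppressWarnings(min(v[!m])), suppressWarnings(max(v[!m]))))
    if (is(object, "DNSTrack"))
        cat(sprintf("  genome mean %.5g, SD %.5g; provenance: %s\n",
                    object@genomeMean, object@genomeSD,
                    paste(object@provenance, collapse = "+")))
})

## congruence check for binary track operations
stopIfNotCongruent <- function(a, b) {
    if (!identical(a@assembly@chroms, b@assembly@chroms) ||
        !identical(unname(a@assembly@lengths), unname(b@assembly@lengths)) ||
        a@binWidth != b@binWidth)
        stop("tracks are not congruent (assembly or bin width differ)")
    invisible(TRUE)
}

## apply f(values, values, ...) per chromosome over two congruent tracks
trackMap2 <- function(a, b, f, mask = "or") {
    stopIfNotCongruent(a, b)
    vals <- mapply(f, a@values, b@values, SIMPLIFY = FALSE)
    msk <- switch(mask,
        or = mapply(`|`, a@mask, b@mask, SIMPLIFY = FALSE),
        and = mapply(`&`, a@mask, b@mask, SIMPLIFY = FALSE))
    new("BinTrack", assembly = a@assembly, binWidth = a@binWidth,
        values = vals, mask = msk)
}

unmaskedValues <- function(track) {
    v <- unlist(track@values, use.names = FALSE)
    m <- unlist(track@mask, use.names = FALSE)
    v[!m]
}

## population SD
popSD <- function(x) {
    mu <- mean(x)
    sqrt(mean((x - mu)^2))
}

#' Bin read coverage at fixed width
#'
#' Counts, for every fixed-width bin, the number of read intervals
#' overlapping the bin by at least 1 bp (the semantics of
#' \code{bedmap --count} with the bin as the reference element); a read
#' spanning several bins is counted once in each.
#'
#' @param reads GRanges of aligned read/fragment intervals.
#' @param assembly a GenomeAssembly; reads must lie within it.
#' @param binWidth bin width in bp (default 10).
#' @return a \linkS4class{BinTrack} of raw counts (nothing masked).
#' @examples
#' asm <- GenomeAssembly("1A", 100)
#' rd <- GenomicRanges::GRanges("1A", IRanges::IRanges(6, 25))
#' trackValues(binCoverage(rd, asm))$`1A`
#' @export
binCoverage <- function(reads, assembly, binWidth = 10L) {
    binWidth <- as.integer(binWidth)
    if (length(reads) == 0L)
        warning("empty read list: returning all-zero coverage track")
    else
        checkWithinAssembly(reads, assembly, "read")
    nb <- nBinsOf(assembly, binWidth)
    chr <- as.character(seqnames(reads))
    s <- start(reads); e <- end(reads)
    first <- (s - 1L) %/% binWidth + 1L
    last <- (e - 1L) %/% binWidth + 1L
    vals <- lapply(assembly@chroms, function(ch) {
        n <- nb[[ch]]
        i <- chr == ch
        if (!any(i)) return(numeric(n))
        up <- tabulate(first[i], nbins = n + 1L)
        dn <- tabulate(last[i] + 1L, nbins = n + 1L)
        cumsum(up - dn)[seq_len(n)]
    })
    names(vals) <- assembly@chroms
    BinTrack(assembly, values = vals, binWidth = binWidth)
}

#' Counts-per-million normalization
#'
#' Divides every bin value by \code{totalMapped / 1e6}, the per-million
#' scaling used before the light-minus-heavy subtraction.
#'
#' @param track a BinTrack of raw counts.
#' @param totalMapped total uniquely mapped reads genome-wide (> 0).
#' @return a BinTrack of normalized coverage.
#' @export
normalizeCpm <- function(track, totalMapped) {
    if (!is.finite(totalMapped) || totalMapped <= 0)
        stop("totalMapped must be a positive number")
    f <- totalMapped / 1e6
    new("BinTrack", assembly = track@assembly, binWidth = track@binWidth,
        values = lapply(track@values, function(v) v / f), mask = track@mask)
}

#' DNS score: light minus heavy normalized coverage
#'
#' Per-bin difference between the per-million normalized light-digest and
#' heavy-digest coverage. Positive = MNase hyper-sensitive (open),
#' negative = hyper-resistant (closed).
#'
#' @param light,heavy congruent normalized BinTracks.
#' @return a BinTrack of DNS scores; a bin is masked if masked in either
#'   input.
#' @export
dnsScore <- function(light, heavy) {
    trackMap2(light, heavy, `-`, mask = "or")
}

#' Average replicate DNS tracks
#'
#' Per-bin arithmetic mean over one or more congruent tracks; genome-wide
#' mean and population SD are computed over the unmasked bins of the
#' averaged track (a bin is masked if masked in any input).
#'
#' @param tracks list of congruent BinTracks.
#' @param provenance character labels for the replicates averaged.
#' @return a \linkS4class{DNSTrack}.
#' @export
averageReplicates <- function(tracks, provenance = as.character(seq_along(tracks))) {
    if (length(tracks) < 1L) stop("need at least one track")
    for (t in tracks[-1]) stopIfNotCongruent(tracks[[1]], t)
    k <- length(tracks)
    vals <- lapply(seq_along(tracks[[1]]@values), function(i) {
        Reduce(`+`, lapply(tracks, function(t) t@values[[i]])) / k
    })
    msk <- lapply(seq_along(tracks[[1]]@mask), function(i) {
        Reduce(`|`, lapply(tracks, function(t) t@mask[[i]]))
    })
    names(vals) <- names(msk) <- tracks[[1]]@assembly@chroms
    v <- unlist(vals, use.names = FALSE)[!unlist(msk, use.names = FALSE)]
    if (!length(v)) stop("all bins masked: cannot compute genome moments")
    new("DNSTrack", assembly = tracks[[1]]@assembly,
        binWidth = tracks[[1]]@binWidth, values = vals, mask = msk,
        provenance = provenance, genomeMean = mean(v), genomeSD = popSD(v))
}

#' Promote a BinTrack to a DNSTrack (computing genome moments)
#' @param track a BinTrack.
#' @param provenance label.
#' @return a DNSTrack.
#' @export
asDNSTrack <- function(track, provenance = "1") {
    if (is(track, "DNSTrack")) return(track)
    averageReplicates(list(track), provenance = provenance)
}

#' Replicate correlation
#'
#' Pearson correlation between two congruent tracks over bins unmasked in
#' both (i.e. bins with digest signal in at least one sample). With
#' \code{window}, bin values are first averaged in tiling windows and the
#' correlation is computed over window means.
#'
#' @param a,b congruent BinTracks.
#' @param window optional window size in bp for window-level correlation.
#' @return Pearson r, or NA if fewer than 2 eligible bins.
#' @export
replicateCorrelation <- function(a, b, window = NULL) {
    stopIfNotCongruent(a, b)
    if (!is.null(window)) {
        wa <- windowSummary(a, window)
        wb <- windowSummary(b, window)
        x <- wa$mean; y <- wb$mean
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 2L) return(NA_real_)
        return(cor(x[ok], y[ok]))
    }
    va <- unlist(a@values, use.names = FALSE)
    vb <- unlist(b@values, use.names = FALSE)
    ok <- !(unlist(a@mask, use.names = FALSE) | unlist(b@mask, use.names = FALSE))
    if (sum(ok) < 2L) return(NA_real_)
    cor(va[ok], vb[ok])
}

## prefix sums over unmasked bins, used by aggregateTrack/windowSummary
trackPrefix <- function(track) {
    lapply(track@assembly@chroms, function(ch) {
        v <- track@values[[ch]]
        u <- !track@mask[[ch]]
        list(S = cumsum(c(0, ifelse(u, v, 0))), C = cumsum(c(0L, as.integer(u))))
    }) |> setNames(track@assembly@chroms)
}

#' Aggregate a track over intervals
#'
#' Statistic over the values of all bins overlapping each interval by at
#' least 1 bp. Means are unweighted over overlapping unmasked bins (the
#' per-10-bp average used to make DNS values comparable across regions);
#' an interval overlapping zero unmasked bins yields NA.
#'
#' @param track a BinTrack.
#' @param intervals GRanges within the assembly.
#' @param stat "mean" or "sum".
#' @return numeric vector, one value per interval.
#' @export
aggregateTrack <- function(track, intervals, stat = c("mean", "sum")) {
    stat <- match.arg(stat)
    if (length(intervals) == 0L) return(numeric(0))
    checkWithinAssembly(intervals, track@assembly)
    w <- track@binWidth
    pre <- trackPrefix(track)
    chr <- as.character(seqnames(intervals))
    first <- (start(intervals) - 1L) %/% w + 1L
    last <- (end(intervals) - 1L) %/% w + 1L
    out <- numeric(length(intervals))
    for (ch in unique(chr)) {
        i <- which(chr == ch)
        S <- pre[[ch]]$S; C <- pre[[ch]]$C
        s <- S[last[i] + 1L] - S[first[i]]
        n <- C[last[i] + 1L] - C[first[i]]
        out[i] <- if (stat == "mean") ifelse(n > 0L, s / n, NA_real_)
                  else ifelse(n > 0L, s, NA_real_)
    }
    out
}

## per-interval sum and unmasked-bin count (internal)
aggregateSumCount <- function(track, intervals) {
    w <- track@binWidth
    pre <- trackPrefix(track)
    chr <- as.character(seqnames(intervals))
    first <- (start(intervals) - 1L) %/% w + 1L
    last <- (end(intervals) - 1L) %/% w + 1L
    s <- numeric(length(intervals)); n <- numeric(length(intervals))
    for (ch in unique(chr)) {
        i <- which(chr == ch)
        s[i] <- pre[[ch]]$S[last[i] + 1L] - pre[[ch]]$S[first[i]]
        n[i] <- pre[[ch]]$C[last[i] + 1L] - pre[[ch]]$C[first[i]]
    }
    data.frame(sum = s, count = n)
}

#' Window summary of a track
#'
#' Mean track value in tiling (step = window) or sliding (step < window)
#' windows. Tiling keeps a flagged partial terminal window; sliding
#' windows are full-width only.
#'
#' @param track a BinTrack.
#' @param window window size in bp (multiple of the bin width).
#' @param step step in bp (default = window, i.e. tiling).
#' @return GRanges of windows with mcols \code{mean}, \code{nBins}
#'   (unmasked bins) and \code{partial}.
#' @export
windowSummary <- function(track, window, step = window) {
    w <- track@binWidth
    if (window %% w != 0 || step %% w != 0)
        stop("window and step must be multiples of the bin width")
    if (window < w) stop("window must be >= bin width")
    pre <- trackPrefix(track)
    asm <- track@assembly
    res <- lapply(asm@chroms, function(ch) {
        len <- asm@lengths[[ch]]
        starts <- seq(1, max(1, len - window + 1), by = step)
        ends <- pmin(starts + window - 1, len)
        partial <- ends - starts + 1 < window
        if (step == window && max(ends) < len) {      # trailing partial tile
            starts <- c(starts, max(ends) + 1)
            ends <- c(ends, len)
            partial <- c(partial, TRUE)
        } else if (step < window) {
            keep <- !partial
            starts <- starts[keep]; ends <- ends[keep]; partial <- partial[keep]
        }
        if (!length(starts)) return(NULL)
        first <- (starts - 1) %/% w + 1
        last <- (ends - 1) %/% w + 1
        S <- pre[[ch]]$S; C <- pre[[ch]]$C
        s <- S[last + 1] - S[first]
        n <- C[last + 1] - C[first]
        data.frame(chrom = ch, start = starts, end = ends,
                   mean = ifelse(n > 0, s / n, NA_real_),
                   nBins = n, partial = partial)
    })
    res <- do.call(rbind, res)
    gr <- GRanges(res$chrom, IRanges(res$start, res$end),
                  seqinfo = asSeqinfo(asm))
    mcols(gr)$mean <- res$mean
    mcols(gr)$nBins <- res$nBins
    mcols(gr)$partial <- res$partial
    gr
}

#' Run the DNS core pipeline on four digest samples
#'
#' From two replicates of light/heavy digest read sets to per-replicate
#' and replicate-averaged DNS tracks: 10-bp binning, per-million
#' normalization, light-minus-heavy subtraction, replicate averaging and
#' correlation. Bins with zero raw coverage in all samples are masked from
#' genome-wide moments and from the replicate correlation.
#'
#' @param samples list of four \linkS4class{DigestSample}s (replicates 1-2
#'   x light/heavy).
#' @param assembly a GenomeAssembly.
#' @param binWidth bin width in bp.
#' @return list with elements \code{norm} (named normalized coverage
#'   tracks), \code{dnsReps} (per-replicate DNS BinTracks), \code{dns}
#'   (averaged \linkS4class{DNSTrack}), \code{replicateR}, and
#'   \code{summary} (per-sample data.frame).
#' @export
dnsPipeline <- function(samples, assembly, binWidth = 10L) {
    key <- vapply(samples, function(s)
        paste0(s@digest, s@replicate), character(1))
    names(samples) <- key
    need <- c("light1", "heavy1", "light2", "heavy2")
    if (!all(need %in% key))
        stop("need samples light/heavy x replicates 1 and 2; got: ",
             paste(key, collapse = ", "))
    raw <- lapply(samples, function(s) binCoverage(s@reads, assembly, binWidth))
    ## mask: no raw signal in any sample
    msk <- lapply(assembly@chroms, function(ch) {
        Reduce(`&`, lapply(raw, function(t) t@values[[ch]] == 0))
    })
    names(msk) <- assembly@chroms
    norm <- lapply(key, function(k) {
        t <- normalizeCpm(raw[[k]], samples[[k]]@totalMapped)
        t@mask <- msk
        t
    })
    names(norm) <- key
    dnsReps <- list(`1` = dnsScore(norm$light1, norm$heavy1),
                    `2` = dnsScore(norm$light2, norm$heavy2))
    dns <- averageReplicates(dnsReps, provenance = c("1", "2"))
    r <- replicateCorrelation(dnsReps[[1]], dnsReps[[2]])
    summary <- data.frame(
        sample = key,
        replicate = vapply(samples, slot, integer(1), "replicate"),
        digest = vapply(samples, slot, character(1), "digest"),
        totalMapped = vapply(samples, slot, numeric(1), "totalMapped"),
        reads = vapply(samples, function(s) length(s@reads), integer(1)))
    list(norm = norm, dnsReps = dnsReps, dns = dns, replicateR = r,
         summary = summary)
}

#' Construct a DigestSample
#' @param replicate replicate id (1 or 2).
#' @param digest "light" or "heavy".
#' @param reads GRanges of aligned fragment intervals.
#' @param totalMapped total uniquely mapped reads (default: number of
#'   reads supplied).
#' @return a \linkS4class{DigestSample}.
#' @export
DigestSample <- function(replicate, digest, reads,
                         totalMapped = length(reads)) {
    new("DigestSample", replicate = as.integer(replicate),
        digest = digest, reads = reads, totalMapped = as.numeric(totalMapped))
}
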