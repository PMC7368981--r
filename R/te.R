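#' DNS scores for TE superfamilies and families
#'
#' Each TE gets the unweighted mean DNS over the 10-bp bins of its span;
#' groups (superfamily or family, by subgenome) then report the mean and
#' sample SD across their elements, plus a bp-weighted track mean for
#' reference.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param tes GRanges from \code{\link{readTEAnnotation}}.
#' @param by "superfamily" or "family".
#' @return data.frame (group, subgenome, n, mean, sd, bpWeightedMean).
#' @export
teScores <- function(dns, tes, by = c("superfamily", "family")) {
    by <- match.arg(by)
    mv <- aggregateTrack(dns, tes, "mean")
    sc <- aggregateSumCount(dns, tes)
    grp <- mcols(tes)[[by]]
    sg <- subgenomeOf(dns@assembly, as.character(seqnames(tes)))
    key <- paste(grp, sg, sep = "\r")
    rows <- lapply(split(seq_along(tes), key), function(i) {
        v <- mv[i]
        v <- v[is.finite(v)]
        if (!length(v)) return(NULL)
        data.frame(group = grp[i[1]], subgenome = sg[i[1]],
                   n = length(v), mean = mean(v), sd = sd(v),
                   bpWeightedMean = sum(sc$sum[i]) / sum(sc$count[i]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$group, out$subgenome), ]
}

#' Spearman correlation of Gypsy content and DNS in sliding windows
#'
#' Per 1-Mb sliding window (200-kb step): the fraction of window bp
#' covered by Gypsy (RLG) elements and the mean DNS; Spearman's rho is
#' computed per subgenome over windows containing at least one Gypsy
#' element.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param tes GRanges from \code{\link{readTEAnnotation}}.
#' @param window,step window and step in bp.
#' @param superfamily TE superfamily whose content is correlated
#'   (default "RLG", Gypsy).
#' @return data.frame (subgenome, n, rho, p); rho NA with fewer than 3
#'   eligible windows or constant content.
#' @export
gypsyDnsCorrelation <- function(dns, tes, window = 1e6, step = 2e5,
                                superfamily = "RLG") {
    win <- windowSummary(dns, window, step)
    cov <- reduce(granges(tes[tes$superfamily == superfamily]),
                  ignore.strand = TRUE)
    ov <- findOverlaps(win, cov)
    clippedBp <- width(pintersect(win[queryHits(ov)], cov[subjectHits(ov)]))
    frac <- numeric(length(win))
    agg <- tapply(clippedBp, queryHits(ov), sum)
    frac[as.integer(names(agg))] <- as.numeric(agg) / width(win)[as.integer(names(agg))]
    sg <- subgenomeOf(dns@assembly, as.character(seqnames(win)))
    rows <- lapply(sort(unique(sg)), function(g) {
        sel <- sg == g & frac > 0 & is.finite(win$mean)
        if (sum(sel) < 3 || length(unique(frac[sel])) == 1L)
            return(data.frame(subgenome = g, n = sum(sel), rho = NA_real_,
                              p = NA_real_))
        ct <- suppressWarnings(stats::cor.test(frac[sel], win$mean[sel],
                                               method = "spearman"))
        data.frame(subgenome = g, n = sum(sel), rho = unname(ct$estimate),
                   p = ct$p.value)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' TE DNS within versus outside promoters
#'
#' Promoters are the strand-aware 2-kb windows upstream of the CDS start;
#' a TE is "within" if its interval overlaps any promoter by >= 1 bp.
#' Per superfamily and subgenome: group means and a Mann-Whitney test.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param tes GRanges from \code{\link{readTEAnnotation}}.
#' @param genes GRanges of gene models.
#' @param radius promoter size in bp (default 2000).
#' @return data.frame (superfamily, subgenome, nWithin, nOutside,
#'   meanWithin, meanOutside, p).
#' @export
promoterTeComparison <- function(dns, tes, genes, radius = 2000) {
    prom <- cdsFlank(genes, radius, "upstream")
    within <- countOverlaps(tes, prom, ignore.strand = TRUE) > 0
    mv <- aggregateTrack(dns, tes, "mean")
    sg <- subgenomeOf(dns@assembly, as.character(seqnames(tes)))
    key <- paste(tes$superfamily, sg, sep = "\r")
    rows <- lapply(split(seq_along(tes), key), function(i) {
        vi <- mv[i][within[i] & is.finite(mv[i])]
        vo <- mv[i][!within[i] & is.finite(mv[i])]
        p <- if (length(vi) >= 2 && length(vo) >= 2)
            wilcox.test(vi, vo, exact = FALSE)$p.value else NA_real_
        data.frame(superfamily = tes$superfamily[i[1]], subgenome = sg[i[1]],
                   nWithin = length(vi), nOutside = length(vo),
                   meanWithin = mean(vi), meanOutside = mean(vo), p = p)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Gene DNS and expression by TE proximity
#'
#' Genes are classed "TE-near" when any TE lies within \code{radius} bp
#' of the gene model (overlap included), overall and stratified by TE
#' class (1 = retro, 2 = DNA). Gene-body DNS and log10 expression are
#' compared between near and far genes (Mann-Whitney).
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param expression named numeric vector of tpm.
#' @param tes GRanges from \code{\link{readTEAnnotation}}.
#' @param genes GRanges of gene models.
#' @param radius bp (default 2000).
#' @param minTpm expression floor for the expression comparison.
#' @return data.frame (te_class, measure, nNear, nFar, meanNear, meanFar,
#'   p); te_class "any" pools the classes.
#' @export
geneTeProximityEffect <- function(dns, expression, tes, genes,
                                  radius = 2000, minTpm = 0.1) {
    body <- aggregateTrack(dns, genes, "mean")
    tpm <- expression[genes$gene_id]
    ltpm <- ifelse(!is.na(tpm) & tpm >= minTpm, log10(tpm), NA)
    nearBy <- function(sub) {
        hit <- distanceToNearest(granges(genes), granges(sub),
                                 ignore.strand = TRUE)
        near <- rep(FALSE, length(genes))
        near[queryHits(hit)] <- mcols(hit)$distance <= radius
        near
    }
    classes <- list(any = tes,
                    `1` = tes[tes$te_class == "1"],
                    `2` = tes[tes$te_class == "2"])
    rows <- list()
    for (cl in names(classes)) {
        if (!length(classes[[cl]])) {
            near <- rep(FALSE, length(genes))
        } else near <- nearBy(classes[[cl]])
        for (ms in c("gene_body_dns", "log10_tpm")) {
            v <- if (ms == "gene_body_dns") body else ltpm
            vn <- v[near & is.finite(v)]
            vf <- v[!near & is.finite(v)]
            p <- if (length(vn) >= 2 && length(vf) >= 2)
                wilcox.test(vn, vf, exact = FALSE)$p.value else NA_real_
            rows[[paste(cl, ms)]] <- data.frame(
                te_class = cl, measure = ms, nNear = length(vn),
                nFar = length(vf), meanNear = mean(vn), meanFar = mean(vf),
                p = p)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
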