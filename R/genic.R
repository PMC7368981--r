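## Map each gene to the global bin indices of its strand-oriented window
## around the CDS start (K bins per side). Returns an n x 2K integer
## matrix (NA where the window leaves the chromosome) with attribute
## "offsets" = window-start offsets in bp (-K*w .. (K-1)*w).
geneWindowBins <- function(track, genes, K) {
    w <- track@binWidth
    asm <- track@assembly
    nb <- nBinsOf(asm, w)
    cum <- setNames(c(0, cumsum(as.numeric(nb)))[seq_along(nb)], names(nb))
    chrom <- as.character(seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    anchor <- ifelse(plus, genes$cds_start, genes$cds_end)
    b <- (anchor - 1) %/% w + 1
    k <- -K:(K - 1)
    rel <- outer(ifelse(plus, 1, -1), k)          # n x 2K signed bin offsets
    binm <- b + rel
    valid <- binm >= 1 & binm <= nb[chrom]
    glob <- cum[chrom] + binm
    glob[!valid] <- NA
    attr(glob, "offsets") <- k * w
    glob
}

#' Metagene DNS profile around the CDS start
#'
#' Mean DNS per 10-bp window at strand-oriented offsets from -flank to
#' +flank around the CDS start (negative = upstream). Genes too close to
#' a chromosome end contribute only their covered offsets.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param genes GRanges of gene models.
#' @param flank flank in bp (multiple of the bin width; default 1000).
#' @return data.frame with columns \code{offset} (bp of window start
#'   relative to the CDS start), \code{mean}, \code{count}.
#' @export
metageneProfile <- function(dns, genes, flank = 1000) {
    w <- dns@binWidth
    if (flank %% w != 0) stop("flank must be a multiple of the bin width")
    if (!length(genes)) stop("no eligible genes")
    K <- flank %/% w
    glob <- geneWindowBins(dns, genes, K)
    V <- unlist(dns@values, use.names = FALSE)
    M <- unlist(dns@mask, use.names = FALSE)
    vals <- matrix(V[glob], nrow = nrow(glob))
    vals[is.na(glob)] <- NA
    vals[!is.na(glob) & M[replace(glob, is.na(glob), 1L)]] <- NA
    data.frame(offset = attr(glob, "offsets"),
               mean = colMeans(vals, na.rm = TRUE),
               count = colSums(!is.na(vals)))
}

#' Per-gene mean DNS in regions a, b, c, d around the CDS start
#'
#' Four strand-oriented 500-bp intervals: a = (-1000,-500], b = (-500,0],
#' c = (0,+500], d = (+500,+1000] relative to the CDS start. Genes whose
#' full 2-kb window leaves the chromosome are excluded (fixed-width
#' comparison across subgenomes).
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param genes GRanges of gene models.
#' @return data.frame gene_id, subgenome, a, b, c, d.
#' @export
regionABCD <- function(dns, genes) {
    w <- dns@binWidth
    K <- 1000 %/% w
    glob <- geneWindowBins(dns, genes, K)
    full <- rowSums(is.na(glob)) == 0
    glob <- glob[full, , drop = FALSE]
    genes <- genes[full]
    if (!length(genes))
        return(data.frame(gene_id = character(0), subgenome = character(0),
                          a = numeric(0), b = numeric(0), c = numeric(0),
                          d = numeric(0)))
    V <- unlist(dns@values, use.names = FALSE)
    M <- unlist(dns@mask, use.names = FALSE)
    vals <- matrix(V[glob], nrow = nrow(glob), ncol = ncol(glob))
    vals[M[glob]] <- NA
    half <- 500 %/% w
    reg <- list(a = 1:half, b = half + 1:half,
                c = 2 * half + 1:half, d = 3 * half + 1:half)
    out <- data.frame(
        gene_id = genes$gene_id,
        subgenome = subgenomeOf(dns@assembly, as.character(seqnames(genes))))
    for (r in names(reg))
        out[[r]] <- rowMeans(vals[, reg[[r]], drop = FALSE], na.rm = TRUE)
    out
}

#' Mean DNS over the five genic partitions
#'
#' Per-gene means over the whole gene model, 500 bp upstream of the CDS,
#' 2 kb upstream of the CDS and 2 kb downstream of the CDS
#' (strand-oriented; windows truncated at chromosome ends are scored over
#' the existing part and flagged), plus per-block means over the
#' intergenic space (the complement of gene models extended by 2 kb).
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param genes GRanges of gene models.
#' @return list: \code{genes} data.frame (gene_id, gene_body,
#'   upstream_500, upstream_2kb, downstream_2kb, truncated),
#'   \code{intergenic} GRanges with mcol \code{meanDNS}.
#' @export
genicPartitionScores <- function(dns, genes) {
    body <- aggregateTrack(dns, genes, "mean")
    up500 <- cdsFlank(genes, 500, "upstream")
    up2k <- cdsFlank(genes, 2000, "upstream")
    dn2k <- cdsFlank(genes, 2000, "downstream")
    fill <- function(fl) {
        v <- setNames(rep(NA_real_, length(genes)), genes$gene_id)
        v[fl$gene_id] <- aggregateTrack(dns, fl, "mean")
        v
    }
    trunc <- function(fl) {
        v <- setNames(rep(TRUE, length(genes)), genes$gene_id)
        v[fl$gene_id] <- fl$truncated
        v
    }
    tab <- data.frame(gene_id = genes$gene_id,
                      gene_body = body,
                      upstream_500 = fill(up500),
                      upstream_2kb = fill(up2k),
                      downstream_2kb = fill(dn2k),
                      truncated = trunc(up2k) | trunc(dn2k),
                      row.names = NULL)
    env <- reduce(expandClip(granges(genes), 2000), ignore.strand = TRUE)
    inter <- gaps(env)
    inter <- inter[strand(inter) == "*"]
    inter <- inter[width(inter) > 0]
    mcols(inter)$meanDNS <- aggregateTrack(dns, inter, "mean")
    list(genes = tab, intergenic = inter)
}

#' Correlation between expression and a per-gene DNS score
#'
#' Pearson r between log10(tpm + pseudocount) and the per-gene score,
#' restricted to expressed genes (mean tpm >= \code{minTpm}).
#'
#' @param scores named numeric vector (gene_id -> region mean DNS).
#' @param expression named numeric vector (gene_id -> tpm).
#' @param minTpm expression floor (default 0.1 tpm).
#' @param pseudocount added to tpm before log10 (default 0; expressed
#'   genes only, so the log is finite).
#' @return list: r, p, n.
#' @export
expressionDnsCorrelation <- function(scores, expression, minTpm = 0.1,
                                     pseudocount = 0) {
    common <- intersect(names(scores), names(expression))
    tpm <- expression[common]
    sc <- scores[common]
    keep <- tpm >= minTpm & is.finite(sc)
    if (sum(keep) < 3) return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
    x <- log10(tpm[keep] + pseudocount)
    y <- sc[keep]
    if (sd(y) == 0 || sd(x) == 0) {
        warning("constant values: correlation undefined")
        return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
    }
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

## default centroid table for the seven homoeolog-bias categories
## (relative contributions rA, rB, rD)
tripletCentroids <- function() {
    rbind(balanced = c(1, 1, 1) / 3,
          A.dominant = c(1, 0, 0),
          B.dominant = c(0, 1, 0),
          D.dominant = c(0, 0, 1),
          A.suppressed = c(0, .5, .5),
          B.suppressed = c(.5, 0, .5),
          D.suppressed = c(.5, .5, 0))
}

#' Categorize homoeolog triplets by relative expression contribution
#'
#' For each A/B/D triplet with summed expression >= \code{minSum} tpm,
#' the relative contributions (rA, rB, rD) are assigned to the nearest of
#' seven centroids (Euclidean distance): balanced, X.dominant,
#' X.suppressed for X in A, B, D. Ties go to balanced.
#'
#' @param triplets data.frame with columns gene_A, gene_B, gene_D.
#' @param expression named numeric vector of tpm.
#' @param minSum minimum summed tpm (default 0.5).
#' @param centroids 7x3 centroid matrix (rows named by category).
#' @return data.frame gene_A, gene_B, gene_D, rA, rB, rD, category.
#' @export
categorizeTriplets <- function(triplets, expression, minSum = 0.5,
                               centroids = tripletCentroids()) {
    ids <- as.matrix(triplets[, c("gene_A", "gene_B", "gene_D")])
    missing <- !ids %in% names(expression)
    if (any(missing)) {
        bad <- rowSums(matrix(missing, nrow = nrow(ids))) > 0
        warning(sum(bad), " triplet(s) with missing expression skipped")
        triplets <- triplets[!bad, , drop = FALSE]
        ids <- ids[!bad, , drop = FALSE]
    }
    tpm <- matrix(expression[ids], nrow = nrow(ids))
    tot <- rowSums(tpm)
    keep <- tot >= minSum
    triplets <- triplets[keep, , drop = FALSE]
    tpm <- tpm[keep, , drop = FALSE]
    if (!nrow(tpm))
        return(data.frame(triplets, rA = numeric(0), rB = numeric(0),
                          rD = numeric(0), category = character(0),
                          row.names = NULL))
    r <- tpm / rowSums(tpm)
    d2 <- sapply(seq_len(nrow(centroids)), function(i)
        rowSums(sweep(r, 2, centroids[i, ])^2))
    d2 <- matrix(d2, ncol = nrow(centroids))
    ibal <- which(rownames(centroids) == "balanced")
    cat <- apply(d2, 1, function(row) {
        best <- which(row <= min(row) + 1e-12)
        if (length(best) > 1) ibal else best
    })
    data.frame(triplets,
               rA = r[, 1], rB = r[, 2], rD = r[, 3],
               category = rownames(centroids)[cat],
               row.names = NULL)
}

#' Intergenomic DNS tests within triplet bias categories
#'
#' For each bias category and each region a/b/c/d: Kruskal-Wallis test of
#' the per-gene region DNS across the three subgenomes, plus pairwise
#' Mann-Whitney tests with Benjamini-Hochberg adjustment over the whole
#' pairwise family.
#'
#' @param categories data.frame from \code{\link{categorizeTriplets}}.
#' @param abcd data.frame from \code{\link{regionABCD}}.
#' @return list: \code{kruskal} data.frame (category, region, H, p, n),
#'   \code{pairwise} data.frame (category, region, g1, g2, W, p, p_adj).
#' @export
tripletBiasTests <- function(categories, abcd) {
    val <- function(ids, region) {
        v <- setNames(abcd[[region]], abcd$gene_id)[ids]
        v[is.finite(v)]
    }
    kw <- list(); pw <- list()
    for (cc in unique(categories$category)) {
        sel <- categories$category == cc
        if (sum(sel) < 2) next
        for (region in c("a", "b", "c", "d")) {
            groups <- list(A = val(categories$gene_A[sel], region),
                           B = val(categories$gene_B[sel], region),
                           D = val(categories$gene_D[sel], region))
            groups <- groups[lengths(groups) >= 2]
            if (length(groups) < 2) next
            kt <- kruskal.test(groups)
            kw[[paste(cc, region)]] <- data.frame(
                category = cc, region = region,
                H = unname(kt$statistic), p = kt$p.value,
                n = sum(lengths(groups)))
            cmb <- utils::combn(names(groups), 2)
            for (j in seq_len(ncol(cmb))) {
                g1 <- cmb[1, j]; g2 <- cmb[2, j]
                wt <- wilcox.test(groups[[g1]], groups[[g2]],
                                  exact = (length(groups[[g1]]) +
                                           length(groups[[g2]])) <= 20)
                pw[[paste(cc, region, g1, g2)]] <- data.frame(
                    category = cc, region = region, g1 = g1, g2 = g2,
                    W = unname(wt$statistic), p = wt$p.value)
            }
        }
    }
    kw <- do.call(rbind, kw); rownames(kw) <- NULL
    pw <- do.call(rbind, pw)
    if (!is.null(pw)) {
        pw$p_adj <- p.adjust(pw$p, "BH")
        rownames(pw) <- NULL
    }
    list(kruskal = kw, pairwise = pw)
}
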