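#' Rank the genome into DNS quantile bins
#'
#' Unmasked 10-bp bins are sorted by DNS score (most closed to most open;
#' ties broken by genomic order) and split into \code{nBins} groups of as
#' near-equal size as possible, each representing 1/nBins of the assayed
#' genome. Group 1 = most closed chromatin, group nBins = most open.
#'
#' @param dns a DNSTrack (or BinTrack).
#' @param nBins number of quantile groups (default 5).
#' @return a BinTrack whose values are group labels (1..nBins; masked
#'   bins keep value 0 and their mask).
#' @export
rankGenomeBins <- function(dns, nBins = 5L) {
    v <- unlist(dns@values, use.names = FALSE)
    m <- unlist(dns@mask, use.names = FALSE)
    idx <- which(!m)
    if (length(idx) < nBins) stop("fewer unmasked bins than groups")
    ord <- idx[order(v[idx], idx)]
    grp <- integer(length(v))
    n <- length(ord)
    grp[ord] <- as.integer(floor((seq_len(n) - 1) * nBins / n) + 1)
    nb <- lengths(dns@values)
    splits <- rep(seq_along(nb), nb)
    vals <- split(as.numeric(grp), splits)
    names(vals) <- names(dns@values)
    BinTrack(dns@assembly, values = vals, binWidth = dns@binWidth,
             mask = dns@mask)
}

## group label of genomic positions (0 for masked/unassigned)
binGroupAt <- function(groups, chrom, pos) {
    w <- groups@binWidth
    b <- (pos - 1) %/% w + 1
    out <- numeric(length(pos))
    for (ch in unique(chrom)) {
        i <- chrom == ch
        g <- groups@values[[ch]][b[i]]
        g[groups@mask[[ch]][b[i]]] <- 0
        out[i] <- g
    }
    out
}

#' Select genic SNPs and assign them to DNS bins
#'
#' Filter order: MAF filter (> \code{maf}), thinning to the first SNP per
#' fixed genomic tile of \code{thin} bp, restriction to gene bodies plus
#' \code{flank} bp, then assignment to the DNS group of the SNP's 10-bp
#' bin (SNPs in masked bins are dropped).
#'
#' @param snps list with \code{positions} (chrom, pos) and \code{geno}
#'   (individuals x SNPs), as from \code{\link{readSnpTable}}.
#' @param genes GRanges of gene models.
#' @param groups BinTrack from \code{\link{rankGenomeBins}}.
#' @param flank genic flank in bp (default 1000).
#' @param thin thinning tile in bp (default 10000).
#' @param maf minor-allele-frequency floor (default 0.002, exclusive).
#' @return list: \code{positions}, \code{geno}, \code{bin} (integer per
#'   SNP).
#' @export
selectSnps <- function(snps, genes, groups, flank = 1000, thin = 10000,
                       maf = 0.002) {
    pos <- snps$positions
    geno <- snps$geno
    p <- colMeans(geno, na.rm = TRUE) / 2
    keep <- pmin(p, 1 - p) > maf & !is.na(p)
    ## thinning: first SNP per fixed genomic tile
    tile <- paste(pos$chrom, (pos$pos - 1) %/% thin)
    ord <- order(pos$chrom, pos$pos)
    first <- ord[!duplicated(tile[ord])]
    keepThin <- logical(nrow(pos)); keepThin[first] <- TRUE
    keep <- keep & keepThin
    ## genic restriction
    env <- reduce(expandClip(granges(genes), flank), ignore.strand = TRUE)
    sngr <- GRanges(pos$chrom, IRanges(pos$pos, pos$pos))
    keep <- keep & countOverlaps(sngr, env) > 0
    bin <- binGroupAt(groups, pos$chrom, pos$pos)
    keep <- keep & bin > 0
    nG <- max(vapply(groups@values, max, numeric(1)))
    nPerBin <- table(factor(bin[keep], levels = seq_len(nG)))
    if (any(nPerBin == 0))
        warning("DNS group(s) without SNPs: ",
                paste(names(nPerBin)[nPerBin == 0], collapse = ", "))
    list(positions = pos[keep, , drop = FALSE],
         geno = geno[, keep, drop = FALSE],
         bin = as.integer(bin[keep]))
}

#' Genomic relationship matrix
#'
#' A = Z Z' / m with Z the column-standardized genotype matrix (per-SNP
#' centering by 2p, scaling by sqrt(2p(1-p))); missing genotypes are
#' mean-imputed per SNP and monomorphic SNPs dropped.
#'
#' @param geno individuals x SNPs matrix coded 0/1/2 (NA allowed).
#' @return n x n symmetric relationship matrix.
#' @export
genomicRelationshipMatrix <- function(geno) {
    p <- colMeans(geno, na.rm = TRUE) / 2
    poly <- !is.na(p) & p > 0 & p < 1
    if (!any(poly)) stop("all SNPs monomorphic")
    geno <- geno[, poly, drop = FALSE]
    p <- p[poly]
    Z <- sweep(geno, 2, 2 * p)
    Z[is.na(Z)] <- 0                      # mean imputation after centering
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    A <- tcrossprod(Z) / ncol(Z)
    (A + t(A)) / 2
}

## profile restricted log-likelihood at log-lambda (internal, eigen form)
remlProfileLL <- function(t, d, ytil, xtil, n) {
    lam <- exp(t)
    w <- lam * d + 1
    xtvx <- sum(xtil^2 / w)
    beta <- sum(xtil * ytil / w) / xtvx
    rss <- sum((ytil - beta * xtil)^2 / w)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xtvx) + (n - 1))
}

#' REML estimate of V(G)/V(p) from a relationship matrix
#'
#' Fits y = mu + g + e with g ~ (0, A sigma_g^2), e ~ (0, I sigma_e^2) by
#' restricted maximum likelihood, profiling over lambda = sigma_g^2 /
#' sigma_e^2 via the eigendecomposition of A and one-dimensional
#' maximization of the restricted likelihood. Returns the heritability
#' sigma_g^2 / (sigma_g^2 + sigma_e^2), clipped to [0, 1] and flagged at
#' the boundary, with a standard error from the curvature of the profile
#' restricted likelihood.
#'
#' @param A symmetric psd relationship matrix.
#' @param y phenotype vector aligned to A (no missing values).
#' @param tol eigenvalue tolerance for the psd check (relative).
#' @return list: vgvp, se, lambda, sigma_g2, sigma_e2, clipped, flat.
#' @export
remlVgVp <- function(A, y, tol = 1e-8) {
    n <- length(y)
    stopifnot(nrow(A) == n, ncol(A) == n)
    eg <- eigen(A, symmetric = TRUE)
    d <- eg$values
    if (min(d) < -tol * max(abs(d)) - 1e-10)
        stop("relationship matrix is not positive semidefinite")
    d <- pmax(d, 0)
    ytil <- drop(crossprod(eg$vectors, y))
    xtil <- drop(crossprod(eg$vectors, rep(1, n)))
    f <- function(t) remlProfileLL(t, d, ytil, xtil, n)
    opt <- optimize(f, interval = c(-25, 25), maximum = TRUE, tol = 1e-9)
    t0 <- opt$maximum
    ## compare against the boundaries of the search interval
    cand <- c(t0, -25, 25)
    ll <- vapply(cand, f, numeric(1))
    t0 <- cand[which.max(ll)]
    lam <- exp(t0)
    h2 <- lam / (1 + lam)
    clipped <- t0 <= -25 + 1e-6 || t0 >= 25 - 1e-6
    ## curvature-based SE on the h2 scale (delta method); a likelihood
    ## that barely moves across the whole lambda range (e.g. A = I, where
    ## the two components are unidentifiable) is flagged flat
    eps <- 1e-3
    ll0 <- f(t0); llp <- f(t0 + eps); llm <- f(t0 - eps)
    d2t <- (llp - 2 * ll0 + llm) / eps^2
    probe <- vapply(seq(-20, 20, by = 5), f, numeric(1))
    flat <- !is.finite(d2t) ||
        diff(range(probe)) < 1e-6 * (1 + abs(ll0))
    se <- if (d2t < 0) {
        dh_dt <- lam / (1 + lam)^2       # dh2/dt with t = log lambda
        sqrt(-1 / d2t) * dh_dt
    } else NA_real_
    w <- lam * d + 1
    beta <- sum(xtil * ytil / w) / sum(xtil^2 / w)
    s2e <- sum((ytil - beta * xtil)^2 / w) / (n - 1)
    list(vgvp = min(1, max(0, h2)), se = se, lambda = lam,
         sigma_g2 = lam * s2e, sigma_e2 = s2e,
         clipped = clipped, flat = flat)
}

#' Variance partitioning across chromatin-accessibility bins
#'
#' For each analyzed DNS bin (default: most closed and most open): sample
#' \code{nSnps} SNPs without replacement, build the GRM, and estimate
#' V(G)/V(p) per trait by REML; repeated \code{reps} times.
#'
#' @param snpSel output of \code{\link{selectSnps}}.
#' @param phenotypes data.frame (individuals x traits), rows aligned to
#'   the genotype matrix rows.
#' @param bins integer bin labels to analyze (default: lowest and highest
#'   present).
#' @param nSnps SNPs sampled per repetition (default 10000; all SNPs,
#'   with a warning, when a bin holds fewer).
#' @param reps repetitions (default 50).
#' @param seed RNG seed.
#' @return data.frame (trait, bin, rep, vgvp, se, clipped) plus a
#'   \code{summary} attribute with per-trait-bin means.
#' @export
partitionExperiment <- function(snpSel, phenotypes, bins = NULL,
                                nSnps = 10000, reps = 50, seed = 1) {
    if (is.null(bins)) bins <- range(snpSel$bin)
    set.seed(seed)
    rows <- list()
    for (b in bins) {
        cols <- which(snpSel$bin == b)
        if (!length(cols)) next
        nDraw <- min(nSnps, length(cols))
        if (nDraw < nSnps)
            warning("bin ", b, ": only ", length(cols),
                    " SNPs available, sampling all")
        for (r in seq_len(reps)) {
            sel <- if (nDraw == length(cols)) cols
                   else sample(cols, nDraw)
            A <- genomicRelationshipMatrix(snpSel$geno[, sel, drop = FALSE])
            for (tr in colnames(phenotypes)) {
                y <- phenotypes[[tr]]
                ok <- is.finite(y)
                fit <- remlVgVp(A[ok, ok, drop = FALSE], y[ok])
                rows[[paste(b, r, tr)]] <- data.frame(
                    trait = tr, bin = b, rep = r, vgvp = fit$vgvp,
                    se = fit$se, clipped = fit$clipped)
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    agg <- stats::aggregate(vgvp ~ trait + bin, data = out, FUN = mean)
    attr(out, "summary") <- agg
    out
}
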