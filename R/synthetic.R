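#' Configuration for the synthetic allopolyploid genome
#'
#' Defaults emulate the statistical structure of a hexaploid DNS-seq
#' study at desk scale: six chromosomes (two homoeologous groups x A/B/D),
#' a telomere-to-centromere accessibility gradient confined to intergenic
#' space, gene density 6-fold higher distally than pericentromerically,
#' TE families with family-specific accessibility effects (Gypsy biased
#' toward the centromere), planted hyper-sensitive/hyper-resistant
#' footprints at a standardized effect of about 3 genome-wide SD, a
#' Cereba-dense CENH3 centromere where both digests lose coverage but
#' light exceeds heavy, homoeolog triplets with planted expression-bias
#' categories linked to promoter accessibility, and phenotypes whose
#' genetic variance concentrates in open-chromatin SNPs.
#'
#' @param ... overrides of the defaults listed below.
#' @return named list of generator settings.
#' @export
syntheticConfig <- function(...) {
    cfg <- list(
        chroms = c("1A", "1B", "1D", "2A", "2B", "2D"),
        chromLength = 8e6,
        binWidth = 10L,
        ## chromosome segments (fractions of length) and centromere
        segmentFractions = c(R1 = 0.2, R2a = 0.25, C = 0.1, R2b = 0.25,
                             R3 = 0.2),
        cenh3Fraction = 0.4,          # central fraction of C
        ## genes
        genesPerMb = 60,
        geneDensityRatio = 6,         # distal : centromeric
        geneLength = 3000,
        cdsMargin = 200,
        minGeneGap = 2200,
        geneSdAccess = 0.35,          # per-gene accessibility deviation SD
        geneWobbleSd = 0.05,          # homoeolog-specific deviation SD
        ## accessibility surface (log digest-rate asymmetry a(x))
        aIntergenicTel = 0.02,
        aIntergenicCen = -0.35,
        aGeneBody = 0.25,
        aPromoter = 0.55,
        flankAmp = 0.35,
        decayKappa = 2000,            # bp, exponential flank decay
        ## TEs
        tesPerMb = 30,
        teFamilies = data.frame(
            family = c("RLG_famc1", "RLG_famc2", "RLC_famc1", "RLX_famc1",
                       "RIX_famc1", "DTC_famc1", "DTM_famc1", "DTT_famc1"),
            beta = c(-0.15, -0.25, 0.15, -0.05, 0, 0.1, 0.05, 0.2),
            weight = c(0.25, 0.15, 0.15, 0.10, 0.05, 0.12, 0.10, 0.08),
            lenMin = 2000, lenMax = 8000),
        cerebaFamily = "RLG_famc7",
        cerebaCover = 0.6,            # fraction of CENH3 covered by Cereba
        cerebaLen = 5000,
        ## planted footprints
        footprintsPerChrom = 17,
        footprintZ = 3,
        footprintLenRange = c(500, 1000),
        footprintMinGeneDist = 3000,
        footprintMinTeDist = 500,
        ## centromere signature
        aCentromere = 0.9,
        depthFactor = 0.3,
        ## triplets / expression
        tripletProportions = c(balanced = 0.25, A.dominant = 0.125,
                               B.dominant = 0.125, D.dominant = 0.125,
                               A.suppressed = 0.125, B.suppressed = 0.125,
                               D.suppressed = 0.125),
        biasFold = 8,                 # dominant x8 / suppressed /8
        aBias = 0.3,                  # promoter/5' accessibility shift
        exprAlpha = 0.5,
        exprGamma = 1.0,
        exprNoiseSd = 0.1,
        msfAdjacentFraction = 0.1,    # genes given a promoter MSF bump
        msfExpressionLift = 1.3,
        aMsfBump = 0.5,
        ## read simulation
        depthRate = 2,                # E fragments / 10-bp bin / sample
        fragLenMean = 150, fragLenSd = 20,
        fragLenRange = c(100, 200))
    over <- list(...)
    stopifnot(all(names(over) %in% names(cfg)))
    cfg[names(over)] <- over
    cfg
}

## telomere->centromere shape: 1 at chromosome ends, 0 at the centromere
## midpoint; evaluated at positions x (bp)
gradientShape <- function(x, len, cenMid) {
    pmin(1, abs(x - cenMid) / max(cenMid - 1, len - cenMid))
}

## sequential gene placement along one chromosome following the density
## gradient; returns start positions
placeGenes <- function(len, cenMid, cfg) {
    dens0 <- cfg$genesPerMb / 1e6
    norm <- 1 + (cfg$geneDensityRatio - 1) / 2
    x <- 1
    starts <- numeric(0)
    repeat {
        d <- dens0 * (1 + (cfg$geneDensityRatio - 1) *
                          gradientShape(x, len, cenMid)) / norm
        gap <- max(cfg$minGeneGap, stats::rexp(1, rate = d))
        x <- x + cfg$geneLength + gap
        if (x + cfg$geneLength > len - 1000) break
        starts <- c(starts, round(x))
    }
    starts
}

binSeqOf <- function(sbp, ebp, w, nb) {
    sbp <- max(1, sbp); ebp <- min(ebp, nb * w)
    if (sbp > ebp) return(integer(0))
    ((sbp - 1) %/% w + 1):((ebp - 1) %/% w + 1)
}

#' Generate the synthetic ground truth
#'
#' Builds the assembly, segments, gene models (with homoeologous
#' triplets), TE annotation, planted footprints, per-bin accessibility
#' surface a(x) (log-asymmetry of light vs heavy digest rates) and
#' centromere signature. The planted footprint effect is derived
#' analytically from the configured sequencing depth so that the expected
#' standardized DNS score of footprint bins is about \code{footprintZ}
#' genome-wide SD.
#'
#' @param config list from \code{\link{syntheticConfig}}.
#' @param seed integer RNG seed; the truth is a deterministic function of
#'   (config, seed).
#' @return list of class \code{SyntheticTruth}.
#' @export
generateTruth <- function(config = syntheticConfig(), seed = 1) {
    cfg <- config
    set.seed(seed)
    w <- cfg$binWidth
    chroms <- cfg$chroms
    lens <- rep(cfg$chromLength, length.out = length(chroms))
    names(lens) <- chroms
    asm <- GenomeAssembly(chroms, lens)
    si <- asSeqinfo(asm)
    stopifnot(abs(sum(cfg$segmentFractions) - 1) < 1e-9)

    ## segments + CENH3
    segRows <- list(); cenRows <- list()
    for (ch in chroms) {
        len <- lens[[ch]]
        bnd <- round(cumsum(c(0, cfg$segmentFractions)) * len)
        s <- GRanges(ch, IRanges(bnd[-6] + 1, bnd[-1]), seqinfo = si)
        mcols(s)$label <- names(cfg$segmentFractions)
        segRows[[ch]] <- s
        C <- s[s$label == "C"]
        cw <- width(C)
        pad <- round(cw * (1 - cfg$cenh3Fraction) / 2)
        cenRows[[ch]] <- GRanges(ch, IRanges(start(C) + pad, end(C) - pad),
                                 seqinfo = si)
    }
    segments <- ChromosomeSegments(do.call(c, unname(segRows)),
                                   do.call(c, unname(cenRows)))
    cenMid <- setNames(
        (start(segments@cenh3) + end(segments@cenh3)) / 2,
        as.character(seqnames(segments@cenh3)))

    ## genes: one template per homoeologous group, jittered per subgenome
    groups <- unique(sub("[A-Z]$", "", chroms))
    geneRows <- list()
    tripRows <- list()
    for (g in groups) {
        gchr <- chroms[startsWith(chroms, g)]
        tmplLen <- lens[[gchr[1]]]
        starts <- placeGenes(tmplLen, cenMid[[gchr[1]]], cfg)
        n <- length(starts)
        strd <- sample(c("+", "-"), n, replace = TRUE)
        u <- rnorm(n, 0, cfg$geneSdAccess)       # shared baseline deviation
        ids <- list()
        for (ch in gchr) {
            sg <- subgenomeOf(asm, ch)
            jit <- round(runif(n, -500, 500))
            s <- starts + jit
            e <- s + cfg$geneLength - 1
            id <- sprintf("G%s%s%04d", g, sg, seq_len(n))
            gr <- GRanges(ch, IRanges(s, e), strand = strd, seqinfo = si)
            mcols(gr)$gene_id <- id
            mcols(gr)$cds_start <- s + cfg$cdsMargin
            mcols(gr)$cds_end <- e - cfg$cdsMargin
            mcols(gr)$confidence <- "HC"
            mcols(gr)$u <- u + rnorm(n, 0, cfg$geneWobbleSd)
            geneRows[[ch]] <- gr
            ids[[sg]] <- id
        }
        if (all(c("A", "B", "D") %in% names(ids)))
            tripRows[[g]] <- data.frame(gene_A = ids$A, gene_B = ids$B,
                                        gene_D = ids$D)
    }
    genes <- do.call(c, unname(geneRows[chroms[chroms %in% names(geneRows)]]))
    triplets <- if (length(tripRows)) do.call(rbind, tripRows)
        else data.frame(gene_A = character(0), gene_B = character(0),
                        gene_D = character(0))
    rownames(triplets) <- NULL

    ## triplet categories: deterministic counts, random assignment
    nT <- nrow(triplets)
    props <- cfg$tripletProportions
    cnt <- floor(props * nT)
    rem <- nT - sum(cnt)
    if (rem > 0) {
        top <- order(props * nT - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[top] <- cnt[top] + 1
    }
    triplets$category <- if (nT) sample(rep(names(props), times = cnt))
        else character(0)

    ## promoter-MSF genes (expression lift markers)
    msfGenes <- sort(sample(genes$gene_id,
                            round(cfg$msfAdjacentFraction * length(genes))))

    ## TEs: placed outside gene envelopes; Gypsy biased to the centromere
    fam <- cfg$teFamilies
    env <- reduce(expandClip(granges(genes), 2000), ignore.strand = TRUE)
    teRows <- list()
    for (ch in chroms) {
        len <- lens[[ch]]
        nTe <- round(cfg$tesPerMb * len / 1e6)
        famIdx <- sample(nrow(fam), nTe, replace = TRUE, prob = fam$weight)
        isRLG <- startsWith(fam$family[famIdx], "RLG")
        pos <- numeric(nTe)
        pos[!isRLG] <- runif(sum(!isRLG), 1, len)
        ## Gypsy biased toward the pericentromere (low gradient shape)
        cand <- runif(sum(isRLG) * 4, 1, len)
        wRLG <- (1 - gradientShape(cand, len, cenMid[[ch]])) + 0.15
        pos[isRLG] <- sample(cand, sum(isRLG), prob = wRLG)
        tlen <- runif(nTe, fam$lenMin[1], fam$lenMax[1])
        s <- pmax(1, round(pos - tlen / 2))
        e <- pmin(len, s + round(tlen) - 1)
        gr <- GRanges(ch, IRanges(s, e), seqinfo = si)
        drop <- countOverlaps(gr, env) > 0
        gr <- gr[!drop]
        famv <- fam$family[famIdx][!drop]
        mcols(gr)$family <- famv
        mcols(gr)$superfamily <- substr(famv, 1, 3)
        mcols(gr)$te_class <- teClassOf(substr(famv, 1, 3))
        mcols(gr)$is_cereba <- FALSE
        mcols(gr)$beta <- fam$beta[famIdx][!drop]
        teRows[[ch]] <- gr
        ## Cereba inside CENH3
        cen <- segments@cenh3[as.character(seqnames(segments@cenh3)) == ch]
        nCer <- max(1, round(width(cen) * cfg$cerebaCover / cfg$cerebaLen))
        cs <- round(seq(start(cen), end(cen) - cfg$cerebaLen,
                        length.out = nCer))
        cgr <- GRanges(ch, IRanges(cs, cs + cfg$cerebaLen - 1), seqinfo = si)
        mcols(cgr)$family <- cfg$cerebaFamily
        mcols(cgr)$superfamily <- substr(cfg$cerebaFamily, 1, 3)
        mcols(cgr)$te_class <- teClassOf(substr(cfg$cerebaFamily, 1, 3))
        mcols(cgr)$is_cereba <- TRUE
        mcols(cgr)$beta <- 0
        teRows[[paste0(ch, ".cer")]] <- cgr
    }
    tes <- sort(do.call(c, unname(teRows)), ignore.strand = TRUE)

    ## ---- accessibility surface ----------------------------------------
    nb <- nBinsOf(asm, w)
    aList <- list()
    geneBlocks <- reduce(granges(genes), ignore.strand = TRUE)
    for (ch in chroms) {
        len <- lens[[ch]]
        n <- nb[[ch]]
        centers <- (seq_len(n) - 0.5) * w
        shp <- gradientShape(centers, len, cenMid[[ch]])
        a <- cfg$aIntergenicCen + (cfg$aIntergenicTel - cfg$aIntergenicCen) * shp
        ## flank decay toward genes
        blk <- geneBlocks[seqnames(geneBlocks) == ch]
        if (length(blk)) {
            bs <- start(blk); be <- end(blk)
            idx <- findInterval(centers, bs)
            dLeft <- ifelse(idx >= 1, centers - be[pmax(idx, 1)], Inf)
            dLeft[idx < 1] <- Inf
            dRight <- ifelse(idx < length(bs), bs[pmin(idx + 1, length(bs))] - centers,
                             Inf)
            inside <- idx >= 1 & centers <= be[pmax(idx, 1)]
            d <- pmin(pmax(dLeft, 0), pmax(dRight, 0))
            d[inside] <- 0
            a <- a + cfg$flankAmp * exp(-d / cfg$decayKappa)
        }
        aList[[ch]] <- a
    }
    ## genic bins: body and promoter levels (override background)
    catOf <- setNames(rep("balanced", length(genes)), genes$gene_id)
    for (cc in names(props)) {
        sel <- triplets$category == cc
        ids <- unlist(triplets[sel, c("gene_A", "gene_B", "gene_D")])
        catOf[ids[ids %in% names(catOf)]] <- cc
    }
    chrOfGene <- as.character(seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    for (i in seq_along(genes)) {
        ch <- chrOfGene[i]
        n <- nb[[ch]]
        gb <- binSeqOf(start(genes)[i], end(genes)[i], w, n)
        ui <- genes$u[i]
        aList[[ch]][gb] <- cfg$aGeneBody + ui
        cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
        pb <- if (plus[i]) binSeqOf(cs - 500, cs - 1, w, n)
              else binSeqOf(ce + 1, ce + 500, w, n)
        aList[[ch]][pb] <- cfg$aPromoter + ui
        gid <- genes$gene_id[i]
        cc <- catOf[[gid]]
        sg <- subgenomeOf(asm, ch)
        if (cc == paste0(sg, ".dominant")) {
            bc <- if (plus[i]) binSeqOf(cs - 500, cs + 499, w, n)
                  else binSeqOf(ce - 499, ce + 500, w, n)
            aList[[ch]][bc] <- aList[[ch]][bc] + cfg$aBias
        } else if (cc == paste0(sg, ".suppressed")) {
            ab <- if (plus[i]) binSeqOf(cs - 1000, cs + 999, w, n)
                  else binSeqOf(ce - 999, ce + 1000, w, n)
            aList[[ch]][ab] <- aList[[ch]][ab] - cfg$aBias
        }
        if (gid %in% msfGenes)
            aList[[ch]][pb] <- aList[[ch]][pb] + cfg$aMsfBump
    }
    ## TE family effects
    chrTe <- as.character(seqnames(tes))
    for (i in which(tes$beta != 0)) {
        ch <- chrTe[i]
        tb <- binSeqOf(start(tes)[i], end(tes)[i], w, nb[[ch]])
        aList[[ch]][tb] <- aList[[ch]][tb] + tes$beta[i]
    }

    ## ---- centromere signature (before the moment computation) ----------
    depthList <- lapply(chroms, function(ch) rep(1, nb[[ch]]))
    names(depthList) <- chroms
    for (ch in chroms) {
        cen <- segments@cenh3[as.character(seqnames(segments@cenh3)) == ch]
        cb <- binSeqOf(start(cen), end(cen), w, nb[[ch]])
        aList[[ch]][cb] <- cfg$aCentromere
        depthList[[ch]][cb] <- cfg$depthFactor
    }

    ## ---- planted footprints (effect derived from depth) ----------------
    ## After per-million normalization each digest has the same genome-wide
    ## mean, so the expected normalized DNS of a bin (in mean-coverage
    ## units) is m d (e^{a/2}/EL - e^{-a/2}/EH) with EL/EH the genome means
    ## of the light/heavy rates; per-bin noise (2-rep average) is Poisson.
    ## Solve for the footprint a that puts the expected standardized score
    ## at +/- footprintZ.
    m <- cfg$depthRate * cfg$fragLenMean / w      # expected per-bin coverage
    aAll <- unlist(aList, use.names = FALSE)
    dAll <- unlist(depthList, use.names = FALSE)
    EL <- mean(dAll * exp(aAll / 2))
    EH <- mean(dAll * exp(-aAll / 2))
    sigf <- function(a, d = 1) m * d * (exp(a / 2) / EL - exp(-a / 2) / EH)
    ## calibrate on the replicate-level standardized scale: the biological
    ## cutoff is applied to each replicate's own z-track
    sig <- sigf(aAll, dAll)
    noiseRep <- mean(m * dAll * (exp(aAll / 2) / EL^2 +
                                 exp(-aAll / 2) / EH^2))
    sdS <- sqrt(noiseRep + var(sig))
    aT <- function(z) stats::uniroot(function(a) sigf(a) - z * sdS,
                                     c(-8, 8))$root
    aMsf <- aT(cfg$footprintZ)
    aMrf <- aT(-cfg$footprintZ)
    fpRows <- list()
    for (ch in chroms) {
        len <- lens[[ch]]
        n <- nb[[ch]]
        centers <- (seq_len(n) - 0.5) * w
        blk <- geneBlocks[seqnames(geneBlocks) == ch]
        ok <- rep(TRUE, n)
        if (length(blk)) {
            near <- reduce(expandClip(blk, cfg$footprintMinGeneDist))
            hit <- findOverlaps(GRanges(ch, IRanges(centers, centers)), near)
            ok[queryHits(hit)] <- FALSE
        }
        cen <- segments@cenh3[as.character(seqnames(segments@cenh3)) == ch]
        ok[binSeqOf(start(cen) - 2000, end(cen) + 2000, w, n)] <- FALSE
        teBlk <- tes[as.character(seqnames(tes)) == ch]
        if (length(teBlk)) {
            teNear <- reduce(expandClip(granges(teBlk), cfg$footprintMinTeDist),
                             ignore.strand = TRUE)
            hit <- findOverlaps(GRanges(ch, IRanges(centers, centers)), teNear)
            ok[queryHits(hit)] <- FALSE
        }
        kinds <- rep(c("MSF", "MRF"), length.out = cfg$footprintsPerChrom)
        lensFp <- round(runif(cfg$footprintsPerChrom,
                              cfg$footprintLenRange[1],
                              cfg$footprintLenRange[2]) / w) * w
        for (j in seq_len(cfg$footprintsPerChrom)) {
            lb <- lensFp[j] %/% w
            repeat {
                b0 <- sample.int(n - lb, 1)
                bins <- b0:(b0 + lb - 1)
                if (all(ok[bins])) break
            }
            ## keep later footprints clear of this one
            ok[max(1, b0 - 50):min(n, b0 + lb + 49)] <- FALSE
            aList[[ch]][bins] <- if (kinds[j] == "MSF") aMsf else aMrf
            fpRows[[paste(ch, j)]] <- data.frame(
                chrom = ch, start = (b0 - 1) * w + 1,
                end = (b0 + lb - 1) * w, kind = kinds[j])
        }
    }
    fpTab <- do.call(rbind, fpRows)
    footprints <- GRanges(fpTab$chrom, IRanges(fpTab$start, fpTab$end),
                          seqinfo = si)
    mcols(footprints)$kind <- fpTab$kind
    mcols(footprints)$a_effect <- ifelse(fpTab$kind == "MSF", aMsf, aMrf)

    truth <- list(
        assembly = asm, segments = segments, genes = genes, tes = tes,
        triplets = triplets, footprints = footprints,
        accessibility = BinTrack(asm, values = aList, binWidth = w),
        depthFactor = BinTrack(asm, values = depthList, binWidth = w),
        msfGenes = msfGenes, geneCategory = catOf,
        footprintEffect = c(MSF = aMsf, MRF = aMrf),
        config = cfg, seed = seed)
    class(truth) <- "SyntheticTruth"
    truth
}

#' @export
print.SyntheticTruth <- function(x, ...) {
    cat("SyntheticTruth:", length(x$assembly@chroms), "chromosomes,",
        length(x$genes), "genes,", length(x$tes), "TEs,",
        length(x$footprints), "planted footprints,",
        nrow(x$triplets), "triplets (seed ", x$seed, ")\n")
    invisible(x)
}

#' Simulate DNS-seq digest samples from the truth
#'
#' Per 10-bp bin and sample, fragment counts are Poisson with rate
#' depth x exp(+a/2) (light) or depth x exp(-a/2) (heavy), scaled by the
#' centromeric depth factor; fragment midpoints are uniform within the
#' bin and fragment lengths clipped-normal (100-200 bp size selection).
#' Expected DNS increases monotonically with a(x); total coverage is
#' a-independent to first order.
#'
#' @param truth from \code{\link{generateTruth}}.
#' @param meanDepth expected fragments per bin per sample (default from
#'   the truth's config; 2 = about 30x base coverage at 150-bp
#'   fragments).
#' @param seed RNG seed.
#' @return list of four \linkS4class{DigestSample}s named light1, heavy1,
#'   light2, heavy2.
#' @export
simulateReads <- function(truth, meanDepth = truth$config$depthRate,
                          seed = 1) {
    set.seed(seed)
    cfg <- truth$config
    asm <- truth$assembly
    w <- cfg$binWidth
    out <- list()
    for (rr in 1:2) for (dig in c("light", "heavy")) {
        sgn <- if (dig == "light") 0.5 else -0.5
        frs <- list()
        for (ch in asm@chroms) {
            a <- truth$accessibility@values[[ch]]
            lam <- meanDepth * exp(sgn * a) * truth$depthFactor@values[[ch]]
            cnt <- rpois(length(lam), lam)
            bin <- rep(seq_along(cnt), cnt)
            mid <- (bin - 1) * w + runif(length(bin)) * w
            fl <- pmin(pmax(rnorm(length(bin), cfg$fragLenMean,
                                  cfg$fragLenSd),
                            cfg$fragLenRange[1]), cfg$fragLenRange[2])
            s <- pmax(1, round(mid - fl / 2))
            e <- pmin(asm@lengths[[ch]], s + round(fl) - 1)
            frs[[ch]] <- GRanges(ch, IRanges(s, e), seqinfo = asSeqinfo(asm))
        }
        reads <- do.call(c, unname(frs))
        out[[paste0(dig, rr)]] <- DigestSample(rr, dig, reads,
                                               totalMapped = length(reads))
    }
    out
}

#' Simulate expression and the triplet table
#'
#' log10 tpm = alpha + gamma x (per-gene accessibility deviation) +
#' noise; dominant homoeologs are multiplied by the bias fold, suppressed
#' homoeologs divided by it, and promoter-MSF genes get the configured
#' expression lift (30 percent by default).
#'
#' @param truth from \code{\link{generateTruth}}.
#' @param seed RNG seed.
#' @return list: \code{expression} (named tpm vector), \code{triplets}
#'   (data.frame gene_A, gene_B, gene_D, category).
#' @export
simulateExpression <- function(truth, seed = 1) {
    set.seed(seed)
    cfg <- truth$config
    genes <- truth$genes
    lt <- cfg$exprAlpha + cfg$exprGamma * genes$u +
        rnorm(length(genes), 0, cfg$exprNoiseSd)
    sg <- subgenomeOf(truth$assembly, as.character(seqnames(genes)))
    cc <- truth$geneCategory[genes$gene_id]
    lt <- lt + ifelse(cc == paste0(sg, ".dominant"), log10(cfg$biasFold),
                      ifelse(cc == paste0(sg, ".suppressed"),
                             -log10(cfg$biasFold), 0))
    lt <- lt + ifelse(genes$gene_id %in% truth$msfGenes,
                      log10(cfg$msfExpressionLift), 0)
    list(expression = setNames(10^lt, genes$gene_id),
         triplets = truth$triplets)
}

#' Simulate genotypes and a phenotype with accessibility-linked variance
#'
#' SNP positions are drawn inside gene bodies +/- 1 kb; genotypes are iid
#' Binomial(2, p), p ~ U(0.05, 0.5). Causal effects are drawn only for
#' SNPs whose 10-bp bin falls in the most open (resp. most closed)
#' quintile of the true accessibility surface, contributing h2_open
#' (resp. h2_closed) of the phenotypic variance; the residual is normal
#' noise.
#'
#' @param truth from \code{\link{generateTruth}}.
#' @param nIndividuals,mSnps panel size.
#' @param h2Open,h2Closed variance fractions (h2Open + h2Closed < 1).
#' @param nCausal number of causal SNPs per quintile (the genotypes carry
#'   no linkage disequilibrium, so a sampled GRM tags only the causal
#'   SNPs it contains; concentrating the genetic variance on a subset
#'   keeps the open/closed contrast detectable under subsampling).
#' @param seed RNG seed.
#' @return list: \code{snps} (positions, geno), \code{phenotypes}
#'   (data.frame, one trait), \code{truthBin} (accessibility quintile per
#'   SNP), \code{causal} (logical per SNP).
#' @export
simulateGenotypesPhenotypes <- function(truth, nIndividuals = 200,
                                        mSnps = 5000, h2Open = 0.5,
                                        h2Closed = 0.1, nCausal = 200,
                                        seed = 1) {
    stopifnot(h2Open + h2Closed < 1)
    set.seed(seed)
    asm <- truth$assembly
    w <- truth$config$binWidth
    genes <- truth$genes
    gi <- sample(length(genes), mSnps, replace = TRUE)
    off <- round(runif(mSnps, -1000, width(genes)[gi] + 1000))
    pos <- pmin(pmax(start(genes)[gi] + off, 1),
                asm@lengths[as.character(seqnames(genes))[gi]])
    chrom <- as.character(seqnames(genes))[gi]
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    ## accessibility quintile of each SNP's bin
    aAll <- unlist(truth$accessibility@values, use.names = FALSE)
    qs <- quantile(aAll, c(0.2, 0.8))
    aSnp <- mapply(function(ch, p) truth$accessibility@values[[ch]][(p - 1) %/% w + 1],
                   chrom, pos)
    bin5 <- ifelse(aSnp <= qs[1], 1L, ifelse(aSnp > qs[2], 5L, 3L))
    p <- runif(mSnps, 0.05, 0.5)
    geno <- matrix(rbinom(nIndividuals * mSnps, 2, rep(p, each = nIndividuals)),
                   nrow = nIndividuals)
    colnames(geno) <- paste0(chrom, ":", pos)
    rownames(geno) <- sprintf("ind%03d", seq_len(nIndividuals))
    causal <- logical(mSnps)
    gval <- function(pool, h2) {
        if (!length(pool) || h2 <= 0) return(rep(0, nIndividuals))
        sel <- if (length(pool) > nCausal) sample(pool, nCausal) else pool
        causal[sel] <<- TRUE
        Z <- scale(geno[, sel, drop = FALSE])
        Z[is.na(Z)] <- 0
        g <- drop(Z %*% rnorm(length(sel)))
        if (sd(g) == 0) return(rep(0, nIndividuals))
        g / sd(g) * sqrt(h2)
    }
    gOpen <- gval(which(bin5 == 5L), h2Open)
    gClosed <- gval(which(bin5 == 1L), h2Closed)
    y <- gOpen + gClosed + rnorm(nIndividuals, 0,
                                 sqrt(1 - h2Open - h2Closed))
    ph <- data.frame(trait1 = y, row.names = rownames(geno))
    list(snps = list(positions = data.frame(chrom = chrom, pos = pos),
                     geno = geno),
         phenotypes = ph, truthBin = bin5,
         causal = causal)
}

#' Write the synthetic dataset to disk
#'
#' Emits everything the file readers consume: chromosome sizes TSV, genes
#' GFF3, TEs BED, segments TSV, triplets TSV, planted-footprint BED, a
#' truth JSON (parameters + footprints), plus optional expression TSV,
#' read BEDs, SNP and phenotype TSVs.
#'
#' @param truth from \code{\link{generateTruth}}.
#' @param dir output directory (created).
#' @param expression optional result of \code{\link{simulateExpression}}.
#' @param samples optional result of \code{\link{simulateReads}}.
#' @param gp optional result of
#'   \code{\link{simulateGenotypesPhenotypes}}.
#' @return the directory, invisibly.
#' @export
writeSyntheticData <- function(truth, dir, expression = NULL,
                               samples = NULL, gp = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeChromSizes(truth$assembly, file.path(dir, "assembly.sizes.tsv"))
    writeGeneModelsGff3(truth$genes, file.path(dir, "genes.gff3"))
    writeTEAnnotation(truth$tes, file.path(dir, "tes.bed"))
    writeSegments(truth$segments, file.path(dir, "segments.tsv"))
    write.table(truth$triplets, file.path(dir, "triplets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fp <- granges(truth$footprints)
    mcols(fp)$name <- truth$footprints$kind
    writeIntervals(fp, file.path(dir, "footprints.truth.bed"))
    jsonlite::write_json(
        list(seed = truth$seed,
             footprintEffect = as.list(truth$footprintEffect),
             config = truth$config[!vapply(truth$config, is.data.frame,
                                           logical(1))]),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(expression))
        write.table(data.frame(gene_id = names(expression$expression),
                               tpm = expression$expression),
                    file.path(dir, "expression.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    if (!is.null(samples))
        for (nm in names(samples))
            writeIntervals(samples[[nm]]@reads,
                           file.path(dir, paste0("reads_", nm, ".bed")))
    if (!is.null(gp)) {
        writeSnpTable(gp$snps, file.path(dir, "snps.tsv"))
        write.table(cbind(id = rownames(gp$phenotypes), gp$phenotypes),
                    file.path(dir, "phenotypes.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
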