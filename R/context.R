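## midpoint of each interval as a width-1 GRanges
midpoints <- function(gr) {
    mid <- floor((start(gr) + end(gr)) / 2)
    GRanges(seqnames(gr), IRanges(mid, mid), seqinfo = seqinfo(gr))
}

## strand-aware promoter / downstream windows anchored on the CDS span.
## upstream of CDS start: [cds_start - size, cds_start - 1] on +,
## [cds_end + 1, cds_end + size] on -; truncated at chromosome ends.
cdsFlank <- function(genes, size, side = c("upstream", "downstream")) {
    side <- match.arg(side)
    chrom <- as.character(seqnames(genes))
    len <- seqlengths(seqinfo(genes))[chrom]
    plus <- as.character(strand(genes)) == "+"
    ## left-of-CDS windows hang off cds_start, right-of-CDS windows off
    ## cds_end; strand decides which side is "upstream"
    up <- xor(!plus, side == "upstream")   # TRUE: window left of the CDS
    s <- ifelse(up, genes$cds_start - size, genes$cds_end + 1)
    e <- ifelse(up, genes$cds_start - 1, genes$cds_end + size)
    trunc <- s < 1 | e > len
    s2 <- pmax(s, 1)
    e2 <- pmin(e, len)
    ok <- s2 <= e2
    gr <- GRanges(chrom[ok], IRanges(s2[ok], e2[ok]),
                  strand = strand(genes)[ok], seqinfo = seqinfo(genes))
    mcols(gr)$gene_id <- genes$gene_id[ok]
    mcols(gr)$truncated <- trunc[ok]
    gr
}

#' Assign each footprint to a single genomic context
#'
#' The footprint midpoint decides the context with precedence gene body >
#' 2-kb upstream of the CDS > 2-kb downstream of the CDS (strand-aware) >
#' TE > unannotated intergenic, so context proportions sum to one.
#' \code{precedence = "te-first"} resolves TE before the genic classes.
#'
#' @param footprints GRanges (mcol \code{kind} carried through).
#' @param genes GRanges from \code{\link{readGeneModels}}.
#' @param tes GRanges from \code{\link{readTEAnnotation}}.
#' @param flank genic flank size in bp (default 2000).
#' @param precedence "genic-first" (default) or "te-first".
#' @return data.frame with columns kind, context, te_class, superfamily,
#'   family (NA outside TEs).
#' @export
assignContext <- function(footprints, genes, tes, flank = 2000,
                          precedence = c("genic-first", "te-first")) {
    precedence <- match.arg(precedence)
    mid <- midpoints(footprints)
    n <- length(footprints)
    ctx <- rep("unannotated_intergenic", n)
    teCls <- rep(NA_character_, n)
    teSf <- rep(NA_character_, n)
    teFam <- rep(NA_character_, n)
    inTe <- countOverlaps(mid, tes, ignore.strand = TRUE) > 0
    hitTe <- findOverlaps(mid, tes, ignore.strand = TRUE, select = "first")
    up <- cdsFlank(genes, flank, "upstream")
    dn <- cdsFlank(genes, flank, "downstream")
    inBody <- countOverlaps(mid, genes, ignore.strand = TRUE) > 0
    inUp <- countOverlaps(mid, up, ignore.strand = TRUE) > 0
    inDn <- countOverlaps(mid, dn, ignore.strand = TRUE) > 0
    if (precedence == "genic-first") {
        ctx[inTe] <- "TE"
        ctx[inDn] <- "downstream_2kb"
        ctx[inUp] <- "upstream_2kb"
        ctx[inBody] <- "gene_body"
    } else {
        ctx[inDn] <- "downstream_2kb"
        ctx[inUp] <- "upstream_2kb"
        ctx[inBody] <- "gene_body"
        ctx[inTe] <- "TE"
    }
    isTe <- ctx == "TE"
    idx <- hitTe[isTe]
    teCls[isTe] <- tes$te_class[idx]
    teSf[isTe] <- tes$superfamily[idx]
    teFam[isTe] <- tes$family[idx]
    data.frame(kind = if (!is.null(footprints$kind)) footprints$kind
                      else NA_character_,
               context = ctx, te_class = teCls, superfamily = teSf,
               family = teFam, stringsAsFactors = FALSE)
}

#' Distance from footprints to the nearest gene
#'
#' Distance in bp from the footprint midpoint to the nearest gene-model
#' edge (0 if the midpoint lies inside a gene). The mode is the peak of a
#' Gaussian kernel density estimate on log10(distance + 1) (Silverman
#' bandwidth), back-transformed to bp; DNS-seq distance distributions are
#' heavily right-skewed, so the mode is reported alongside the mean.
#'
#' @param footprints GRanges.
#' @param genes GRanges of gene models.
#' @return list: \code{distances} (numeric, NA when the chromosome has no
#'   gene), \code{mean}, \code{mode}.
#' @export
nearestGeneDistances <- function(footprints, genes) {
    mid <- midpoints(footprints)
    d <- rep(NA_real_, length(mid))
    hit <- distanceToNearest(mid, genes, ignore.strand = TRUE)
    d[queryHits(hit)] <- mcols(hit)$distance
    dd <- d[!is.na(d)]
    mode <- if (length(dd) >= 3) {
        den <- density(log10(dd + 1))
        10^den$x[which.max(den$y)] - 1
    } else NA_real_
    list(distances = d, mean = mean(dd), mode = mode)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of tables as
#' or less probable than the one observed (via \code{stats::fisher.test});
#' the odds ratio reported is the sample odds ratio ad/bc (Inf or 0 at
#' zero cells; p = 1 by convention when a margin is zero).
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return list with \code{table}, \code{odds_ratio}, \code{p}.
#' @export
fisherEnrichment <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == 2), all(tab >= 0))
    storage.mode(tab) <- "double"     # bp-scale counts overflow integers
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        p <- 1
    } else if (sum(tab) <= 1e5) {
        p <- fisher.test(tab)$p.value
    } else {
        ## same definition, evaluated directly on the hypergeometric pmf
        ## (fisher.test's conditional-MLE machinery is needless at bp scale)
        m <- tab[1, 1] + tab[1, 2]; nn <- tab[2, 1] + tab[2, 2]
        k <- tab[1, 1] + tab[2, 1]
        supp <- max(0, k - nn):min(k, m)
        dens <- dhyper(supp, m, nn, k)
        p <- min(1, sum(dens[dens <= dhyper(tab[1, 1], m, nn, k) *
                                 (1 + 1e-7)]))
    }
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    list(table = tab, odds_ratio = or, p = p)
}

#' Genes with footprints nearby
#'
#' A footprint is credited to every gene whose model, extended by
#' \code{radius}, it overlaps (envelope overlap, no uniqueness), matching
#' the "within 2 kb of at least one MSF" accounting.
#'
#' @param footprints GRanges.
#' @param genes GRanges of gene models.
#' @param radius bp (default 2000).
#' @return list: per-gene \code{counts}, \code{pctWithFootprint},
#'   \code{meanPerGene}.
#' @export
genesNearFootprints <- function(footprints, genes, radius = 2000) {
    env <- granges(genes)
    chrom <- as.character(seqnames(env))
    len <- seqlengths(seqinfo(env))[chrom]
    s <- pmax(start(env) - radius, 1)
    e <- pmin(end(env) + radius, len)
    env <- GRanges(chrom, IRanges(s, e), seqinfo = seqinfo(env))
    counts <- countOverlaps(env, footprints, ignore.strand = TRUE)
    list(counts = setNames(counts, genes$gene_id),
         pctWithFootprint = 100 * mean(counts > 0),
         meanPerGene = mean(counts))
}

#' Per-segment DNS means, footprint content and distal-vs-interior tests
#'
#' For every chromosome segment class (and per subgenome): the unweighted
#' per-10-bp mean DNS and the footprint bp per kind. Enrichment of
#' footprints in the distal ends (R1 and R3 combined) versus the interior
#' (R2a, C, R2b) is tested by Fisher's exact test on bp counts (footprint
#' bp vs non-footprint bp).
#'
#' @param dns a DNSTrack.
#' @param footprints consensus footprint GRanges.
#' @param segments a \linkS4class{ChromosomeSegments}.
#' @return list: \code{perSegment} data.frame, \code{distalTests} (one
#'   Fisher result per footprint kind).
#' @export
segmentSummaries <- function(dns, footprints, segments) {
    segs <- segmentRanges(segments)
    labs <- c("R1", "R2a", "C", "R2b", "R3")
    sg <- subgenomeOf(dns@assembly, as.character(seqnames(segs)))
    rows <- list()
    for (lab in labs) {
        for (g in unique(sg)) {
            s <- segs[segs$label == lab & sg == g]
            if (!length(s)) next
            sc <- aggregateSumCount(dns, s)
            segBp <- sum(width(s))
            msf <- sum(width(intersect(granges(footprints[footprints$kind == "MSF"]),
                                       granges(s))))
            mrf <- sum(width(intersect(granges(footprints[footprints$kind == "MRF"]),
                                       granges(s))))
            rows[[paste(lab, g)]] <- data.frame(
                segment = lab, subgenome = g, segmentBp = segBp,
                meanDNS = if (sum(sc$count) > 0)
                    sum(sc$sum) / sum(sc$count) else NA_real_,
                msfBp = msf, mrfBp = mrf)
        }
    }
    perSegment <- do.call(rbind, rows)
    rownames(perSegment) <- NULL
    distal <- perSegment$segment %in% c("R1", "R3")
    tests <- lapply(c(MSF = "msfBp", MRF = "mrfBp"), function(colnm) {
        fpD <- sum(perSegment[[colnm]][distal])
        fpI <- sum(perSegment[[colnm]][!distal])
        bpD <- sum(perSegment$segmentBp[distal])
        bpI <- sum(perSegment$segmentBp[!distal])
        fisherEnrichment(matrix(c(fpD, bpD - fpD, fpI, bpI - fpI), 2,
                                byrow = TRUE))
    })
    list(perSegment = perSegment, distalTests = tests)
}

#' Overlap of footprints with a labelled chromatin-state map
#'
#' Proportion of footprints (by midpoint) falling in each state label,
#' plus "none"; and the mean DNS per state.
#'
#' @param footprints GRanges with mcol kind.
#' @param states GRanges with mcol \code{label}; intervals of different
#'   labels must not overlap.
#' @param dns optional DNSTrack for per-state mean DNS.
#' @return list: \code{proportions} (data.frame kind, state, proportion),
#'   \code{stateDNS} (data.frame state, meanDNS) when dns given.
#' @export
stateOverlap <- function(footprints, states, dns = NULL) {
    if (length(states)) {
        self <- findOverlaps(states, states, ignore.strand = TRUE)
        off <- queryHits(self) != subjectHits(self)
        if (any(off & states$label[queryHits(self)] !=
                      states$label[subjectHits(self)]))
            stop("state intervals of different labels overlap")
    }
    mid <- midpoints(footprints)
    hit <- findOverlaps(mid, states, ignore.strand = TRUE, select = "first")
    lab <- ifelse(is.na(hit), "none", states$label[hit])
    kinds <- unique(footprints$kind)
    allLabs <- c(sort(unique(states$label)), "none")
    props <- do.call(rbind, lapply(kinds, function(k) {
        sel <- footprints$kind == k
        p <- table(factor(lab[sel], levels = allLabs)) / sum(sel)
        data.frame(kind = k, state = allLabs, proportion = as.numeric(p))
    }))
    out <- list(proportions = props)
    if (!is.null(dns) && length(states)) {
        sDNS <- vapply(allLabs[allLabs != "none"], function(l) {
            s <- states[states$label == l]
            mean(aggregateTrack(dns, s, "mean"), na.rm = TRUE)
        }, numeric(1))
        out$stateDNS <- data.frame(state = names(sDNS), meanDNS = sDNS,
                                   row.names = NULL)
    }
    out
}
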