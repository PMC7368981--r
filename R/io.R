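## ---- BED intervals ---------------------------------------------------

#' Read a BED3/BED6 interval file
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention on read. Malformed lines are reported with their
#' line number; intervals outside the assembly raise an error naming the
#' chromosome.
#'
#' @param path BED file.
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @return GRanges (with \code{name}/\code{score} mcols when present;
#'   strand read from column 6 when present).
#' @export
readIntervals <- function(path, assembly) {
    lines <- readLines(path)
    ln <- seq_along(lines)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lines <- lines[keep]; ln <- ln[keep]
    if (!length(lines))
        return(GRanges(seqinfo = asSeqinfo(assembly)))
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 3L))
        stop("malformed BED line ", ln[which(nf < 3L)[1]],
             ": fewer than 3 fields")
    chrom <- vapply(f, `[`, character(1), 1L)
    s0 <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 2L)))
    e0 <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 3L)))
    bad <- is.na(s0) | is.na(e0)
    if (any(bad))
        stop("malformed BED line ", ln[which(bad)[1]],
             ": non-numeric coordinates")
    bad <- s0 >= e0 | s0 < 0
    if (any(bad))
        stop("malformed BED line ", ln[which(bad)[1]],
             ": start must satisfy 0 <= start < end")
    gr <- GRanges(chrom, IRanges(s0 + 1, e0))
    if (all(nf >= 6L)) {
        str <- vapply(f, `[`, character(1), 6L)
        str[!str %in% c("+", "-")] <- "*"
        strand(gr) <- str
    }
    if (all(nf >= 4L)) mcols(gr)$name <- vapply(f, `[`, character(1), 4L)
    if (all(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(
            as.numeric(vapply(f, `[`, character(1), 5L)))
    bindToAssembly(gr, assembly)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open coordinates; BED6 when \code{name} (and
#' optionally \code{score}) metadata or explicit strand is present,
#' BED3 otherwise.
#'
#' @param gr GRanges.
#' @param path output path.
#' @export
writeIntervals <- function(gr, path) {
    chrom <- as.character(seqnames(gr))
    s0 <- sprintf("%.0f", start(gr) - 1)
    e0 <- sprintf("%.0f", end(gr))
    str <- as.character(strand(gr))
    bed6 <- !is.null(mcols(gr)$name) || any(str != "*")
    if (bed6) {
        nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else "."
        sc <- if (!is.null(mcols(gr)$score))
            sprintf("%.6g", mcols(gr)$score) else "0"
        str[str == "*"] <- "."
        out <- paste(chrom, s0, e0, nm, sc, str, sep = "\t")
    } else {
        out <- paste(chrom, s0, e0, sep = "\t")
    }
    writeLines(out, path)
    invisible(path)
}

## ---- bedGraph tracks -------------------------------------------------

#' Write a BinTrack as bedGraph
#'
#' 0-based half-open records; runs of consecutive equal-valued bins are
#' merged; values carry 6 significant digits.
#'
#' @param track a BinTrack.
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
    w <- track@binWidth
    asm <- track@assembly
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in asm@chroms) {
        v <- signif(track@values[[ch]], 6)
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- c(0, ends[-length(ends)]) * w
        endbp <- pmin(ends * w, asm@lengths[[ch]])
        writeLines(paste(ch, sprintf("%.0f", starts),
                         sprintf("%.0f", endbp),
                         sprintf("%.6g", r$values),
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Read a bedGraph file into a BinTrack
#'
#' Records must align to the bin grid (starts/ends multiples of
#' \code{binWidth}, terminal bin excepted). Uncovered bins get value 0 and
#' are masked.
#'
#' @param path bedGraph file.
#' @param assembly a GenomeAssembly.
#' @param binWidth bin width in bp.
#' @return a BinTrack.
#' @export
readTrack <- function(path, assembly, binWidth = 10L) {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("bedGraph needs 4 columns")
    names(tab)[1:4] <- c("chrom", "start", "end", "value")
    bad <- !tab$chrom %in% assembly@chroms
    if (any(bad)) stop("unknown chromosome(s): ",
                       paste(unique(tab$chrom[bad]), collapse = ", "))
    w <- as.integer(binWidth)
    nb <- nBinsOf(assembly, w)
    vals <- lapply(assembly@chroms, function(ch) numeric(nb[[ch]]))
    msk <- lapply(assembly@chroms, function(ch) rep(TRUE, nb[[ch]]))
    names(vals) <- names(msk) <- assembly@chroms
    if (any(tab$start %% w != 0))
        stop("bedGraph record not aligned to the ", w, "-bp bin grid")
    for (ch in unique(tab$chrom)) {
        i <- tab$chrom == ch
        first <- tab$start[i] %/% w + 1
        last <- (tab$end[i] - 1) %/% w + 1
        for (j in seq_along(first)) {
            idx <- first[j]:last[j]
            vals[[ch]][idx] <- tab$value[i][j]
            msk[[ch]][idx] <- FALSE
        }
    }
    BinTrack(assembly, values = vals, binWidth = w, mask = msk)
}

## ---- gene models -----------------------------------------------------

#' Read gene models (GFF3 or TSV)
#'
#' GFF3 input must carry \code{gene} features (attribute ID) and their
#' \code{CDS} children (attribute Parent, pointing at the gene or at an
#' mRNA child of the gene); the CDS span stored per gene is the union of
#' that gene's CDS features. The TSV alternative has columns
#' gene_id, chrom, start, end, strand, cds_start, cds_end, confidence
#' with 1-based closed coordinates.
#'
#' @param path input file (.gff3/.gff or .tsv).
#' @param assembly a GenomeAssembly.
#' @param format "auto", "gff3" or "tsv".
#' @return GRanges of genes (strand set) with mcols \code{gene_id},
#'   \code{cds_start}, \code{cds_end}, \code{confidence}.
#' @export
readGeneModels <- function(path, assembly, format = c("auto", "gff3", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
    if (format == "tsv") {
        tab <- read.delim(path, stringsAsFactors = FALSE)
        gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                      strand = tab$strand)
        mcols(gr)$gene_id <- as.character(tab$gene_id)
        mcols(gr)$cds_start <- as.numeric(tab$cds_start)
        mcols(gr)$cds_end <- as.numeric(tab$cds_end)
        mcols(gr)$confidence <- if ("confidence" %in% names(tab))
            as.character(tab$confidence) else "HC"
    } else {
        feats <- rtracklayer::import(path, format = "gff3")
        type <- as.character(feats$type)
        genes <- feats[type == "gene"]
        cds <- feats[type == "CDS"]
        mrna <- feats[type == "mRNA"]
        par <- vapply(as.list(cds$Parent), function(p)
            if (length(p)) p[[1]] else NA_character_, character(1))
        if (length(mrna)) {
            m2g <- setNames(vapply(as.list(mrna$Parent), `[`, character(1), 1),
                            mrna$ID)
            hit <- par %in% names(m2g)
            par[hit] <- m2g[par[hit]]
        }
        ids <- genes$ID
        cs <- tapply(start(cds), par, min)[ids]
        ce <- tapply(end(cds), par, max)[ids]
        noCds <- is.na(cs)
        if (any(noCds)) {
            warning(sum(noCds), " gene(s) without CDS skipped")
            genes <- genes[!noCds]; cs <- cs[!noCds]; ce <- ce[!noCds]
        }
        if (any(cs < start(genes) | ce > end(genes)))
            stop("CDS outside gene span for gene ",
                 genes$ID[which(cs < start(genes) | ce > end(genes))[1]])
        gr <- GRanges(as.character(seqnames(genes)),
                      IRanges(start(genes), end(genes)),
                      strand = strand(genes))
        mcols(gr)$gene_id <- as.character(genes$ID)
        mcols(gr)$cds_start <- as.numeric(cs)
        mcols(gr)$cds_end <- as.numeric(ce)
        conf <- if (!is.null(genes$confidence))
            as.character(genes$confidence) else "HC"
        mcols(gr)$confidence <- conf
    }
    if (any(as.character(strand(gr)) == "*"))
        stop("gene models must be stranded")
    if (any(mcols(gr)$cds_start > mcols(gr)$cds_end))
        stop("cds_start must be <= cds_end")
    bindToAssembly(gr, assembly)
}

#' Write gene models as GFF3
#' @param genes GRanges as returned by \code{\link{readGeneModels}}.
#' @param path output path.
#' @export
writeGeneModelsGff3 <- function(genes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    chrom <- as.character(seqnames(genes))
    str <- as.character(strand(genes))
    gl <- paste(chrom, "dnsatlas", "gene", start(genes), end(genes), ".",
                str, ".", paste0("ID=", genes$gene_id, ";confidence=",
                                 genes$confidence), sep = "\t")
    cl <- paste(chrom, "dnsatlas", "CDS",
                sprintf("%.0f", genes$cds_start),
                sprintf("%.0f", genes$cds_end), ".", str, "0",
                paste0("ID=", genes$gene_id, ".cds;Parent=", genes$gene_id),
                sep = "\t")
    writeLines(as.vector(rbind(gl, cl)), con)
    invisible(path)
}

## ---- TE annotation ---------------------------------------------------

## Wicker-style class from the 3-letter superfamily code
teClassOf <- function(superfamily) {
    ifelse(startsWith(superfamily, "RL") | superfamily == "RIX", "1",
           ifelse(startsWith(superfamily, "DT") | superfamily == "DXX", "2",
                  "unclassified"))
}

#' Read a TE annotation BED
#'
#' BED6 whose name column encodes "SUPERFAMILY_family" (Wicker
#' nomenclature, e.g. \code{RLG_famc4}); the superfamily is the leading
#' 3-letter code and fixes the TE class (RL*/RIX = class 1 retro,
#' DT*/DXX = class 2 DNA, otherwise unclassified). Cereba membership is a
#' configured family name set (the centromeric Gypsy lineage).
#'
#' @param path BED file.
#' @param assembly a GenomeAssembly.
#' @param cerebaFamilies family names flagged as Cereba.
#' @return GRanges with mcols \code{family}, \code{superfamily},
#'   \code{te_class}, \code{is_cereba}.
#' @export
readTEAnnotation <- function(path, assembly, cerebaFamilies = "RLG_famc7") {
    gr <- readIntervals(path, assembly)
    if (is.null(mcols(gr)$name)) stop("TE BED needs a name column (family)")
    fam <- mcols(gr)$name
    sf <- toupper(substr(fam, 1, 3))
    mcols(gr) <- NULL
    mcols(gr)$family <- fam
    mcols(gr)$superfamily <- sf
    mcols(gr)$te_class <- teClassOf(sf)
    mcols(gr)$is_cereba <- fam %in% cerebaFamilies
    gr
}

#' Write a TE annotation BED
#' @param tes GRanges from \code{\link{readTEAnnotation}} (or the
#'   synthetic generator).
#' @param path output path.
#' @export
writeTEAnnotation <- function(tes, path) {
    out <- granges(tes)
    mcols(out)$name <- tes$family
    writeIntervals(out, path)
}

## ---- chromosome segments ---------------------------------------------

#' Construct ChromosomeSegments
#'
#' @param segments GRanges with mcols \code{label} in
#'   R1/R2a/C/R2b/R3; per chromosome the five segments must be ordered,
#'   non-overlapping and tile the chromosome.
#' @param cenh3 GRanges of CENH3 centromere intervals, one per
#'   chromosome, each contained in that chromosome's C segment.
#' @return a \linkS4class{ChromosomeSegments}.
#' @export
ChromosomeSegments <- function(segments, cenh3) {
    lab <- c("R1", "R2a", "C", "R2b", "R3")
    for (ch in unique(as.character(seqnames(segments)))) {
        s <- segments[seqnames(segments) == ch]
        s <- s[order(start(s))]
        if (!identical(as.character(s$label), lab))
            stop("chromosome ", ch, ": segments must be R1,R2a,C,R2b,R3 in order")
        if (any(start(s)[-1] != end(s)[-5] + 1))
            stop("chromosome ", ch, ": segments must tile the chromosome")
        cen <- cenh3[seqnames(cenh3) == ch]
        if (length(cen) != 1L)
            stop("chromosome ", ch, ": need exactly one CENH3 interval")
        C <- s[s$label == "C"]
        if (start(cen) < start(C) || end(cen) > end(C))
            stop("chromosome ", ch, ": CENH3 interval must lie within C")
    }
    new("ChromosomeSegments", segments = segments, cenh3 = cenh3)
}

#' @rdname ChromosomeSegments
#' @param x a ChromosomeSegments.
#' @export
segmentRanges <- function(x) x@segments

#' @rdname ChromosomeSegments
#' @export
cenh3Ranges <- function(x) x@cenh3

setMethod("show", "ChromosomeSegments", function(object) {
    cat("ChromosomeSegments over",
        length(unique(as.character(seqnames(object@segments)))),
        "chromosomes (R1/R2a/C/R2b/R3 + CENH3)\n")
})

#' Read a chromosome-segment table
#'
#' TSV with header and columns chrom, label, start, end (1-based closed);
#' labels R1, R2a, C, R2b, R3 and CENH3.
#'
#' @param path TSV path.
#' @param assembly a GenomeAssembly.
#' @return a \linkS4class{ChromosomeSegments}.
#' @export
readSegments <- function(path, assembly) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
    mcols(gr)$label <- tab$label
    gr <- bindToAssembly(gr, assembly)
    ChromosomeSegments(gr[gr$label != "CENH3"],
                       granges(gr[gr$label == "CENH3"]))
}

#' Write a chromosome-segment table
#' @param segments a ChromosomeSegments.
#' @param path output path.
#' @export
writeSegments <- function(segments, path) {
    s <- segments@segments
    cen <- segments@cenh3
    tab <- data.frame(
        chrom = c(as.character(seqnames(s)), as.character(seqnames(cen))),
        label = c(as.character(s$label), rep("CENH3", length(cen))),
        start = sprintf("%.0f", c(start(s), start(cen))),
        end = sprintf("%.0f", c(end(s), end(cen))))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## ---- expression / triplets / footprints ------------------------------

#' Read an expression table (TSV: gene_id, tpm)
#' @param path TSV path.
#' @return named numeric vector of mean tpm.
#' @export
readExpression <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (any(tab$tpm < 0)) stop("tpm must be >= 0")
    setNames(as.numeric(tab$tpm), as.character(tab$gene_id))
}

#' Read a homoeolog triplet table (TSV: gene_A, gene_B, gene_D)
#' @param path TSV path.
#' @return data.frame with columns gene_A, gene_B, gene_D.
#' @export
readTriplets <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    tab[, c("gene_A", "gene_B", "gene_D")]
}

#' Write footprints (BED6 + full-precision sidecar TSV)
#'
#' BED name column = MSF/MRF; BED score = mean DNS x 1000 rounded and
#' clamped to the 0..1000 BED range; full-precision means go to
#' \code{<path>.tsv}.
#'
#' @param footprints GRanges with mcols \code{kind}, \code{mean_dns},
#'   \code{mean_z}.
#' @param path BED output path.
#' @export
writeFootprints <- function(footprints, path) {
    bed <- granges(footprints)
    mcols(bed)$name <- footprints$kind
    mcols(bed)$score <- pmax(0, pmin(1000, round(footprints$mean_dns * 1000)))
    writeIntervals(bed, path)
    tab <- data.frame(chrom = as.character(seqnames(footprints)),
                      start = sprintf("%.0f", start(footprints) - 1),
                      end = sprintf("%.0f", end(footprints)),
                      kind = footprints$kind,
                      mean_dns = sprintf("%.10g", footprints$mean_dns),
                      mean_z = sprintf("%.10g", footprints$mean_z))
    write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read footprints from the sidecar TSV written by writeFootprints
#' @param path the BED path given to \code{\link{writeFootprints}}.
#' @param assembly a GenomeAssembly.
#' @return GRanges with mcols kind, mean_dns, mean_z.
#' @export
readFootprints <- function(path, assembly) {
    tab <- read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1, tab$end))
    mcols(gr)$kind <- tab$kind
    mcols(gr)$mean_dns <- as.numeric(tab$mean_dns)
    mcols(gr)$mean_z <- as.numeric(tab$mean_z)
    bindToAssembly(gr, assembly)
}

## ---- SNPs / phenotypes -----------------------------------------------

#' Read a SNP genotype table
#'
#' TSV with header: chrom, pos (1-based), then one column per individual
#' with genotypes coded 0/1/2 (NA allowed).
#'
#' @param path TSV path.
#' @return list with \code{positions} (data.frame chrom, pos) and
#'   \code{geno} (individuals x SNPs matrix).
#' @export
readSnpTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    geno <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
    storage.mode(geno) <- "numeric"
    colnames(geno) <- paste0(tab$chrom, ":", tab$pos)
    list(positions = data.frame(chrom = tab$chrom, pos = tab$pos),
         geno = geno)
}

#' Write a SNP genotype table
#' @param snps list as returned by \code{\link{readSnpTable}}.
#' @param path output path.
#' @export
writeSnpTable <- function(snps, path) {
    tab <- cbind(snps$positions, as.data.frame(t(snps$geno)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a phenotype table (TSV: id, then one column per trait)
#' @param path TSV path.
#' @return data.frame with rownames = individual ids.
#' @export
readPhenotypes <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab[[1]]
    tab[, -1, drop = FALSE]
}
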