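#' Read a gene annotation into a gene model
#'
#' Parses a GTF or GFF3 file and returns one range per record of the requested
#' feature type, as a sorted `GRanges` with `gene_id`, `tss` and `tes`
#' metadata columns. GTF/GFF3 1-based closed coordinates are kept in the
#' 1-based closed convention of `GRanges`; all interval arithmetic in the
#' package uses that convention, converting only at BED/bedGraph boundaries.
#'
#' The TSS is the strand-aware 5' end of the gene (the `start` coordinate for
#' `+` genes, the `end` coordinate for `-` genes) and the TES the 3' end.
#'
#' @param path Path to a GTF (`.gtf`) or GFF3 (`.gff`/`.gff3`) file.
#' @param feature Feature type to keep (column 3), default `"gene"`.
#' @param chrom_sizes Optional named vector of chromosome lengths (or path to
#'   a two-column TSV); when given, it is attached as `seqlengths` and every
#'   gene is checked to fit its chromosome.
#' @return A `GRanges`, sorted by (chrom, start, gene_id), with metadata
#'   columns `gene_id`, `tss`, `tes`.
#' @export
read_annotation <- function(path, feature = "gene", chrom_sizes = NULL) {
  if (!file.exists(path)) pg_stop("annotation file not found: %s", path)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) pg_stop("failed to parse %s: %s",
                                             path, conditionMessage(e)))
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == feature]
  if (length(gr) == 0)
    pg_stop("no '%s' features in %s", feature, path)
  ids <- if (fmt == "gtf") gr$gene_id else gr$ID
  if (is.null(ids) || anyNA(ids))
    pg_stop("every '%s' record needs a %s attribute", feature,
            if (fmt == "gtf") "gene_id" else "ID")
  if (anyDuplicated(ids))
    pg_stop("duplicate gene_id: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*"))
    pg_stop("gene(s) with unknown strand: %s",
            paste(ids[strands == "*"], collapse = ", "))
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = BiocGenerics::strand(gr))
  out$gene_id <- as.character(ids)
  out <- add_tss_tes(out)
  if (!is.null(chrom_sizes)) {
    if (is.character(chrom_sizes) && length(chrom_sizes) == 1)
      chrom_sizes <- read_chrom_sizes(chrom_sizes)
    out <- set_chrom_sizes(out, chrom_sizes)
  }
  sort_genes(out)
}

add_tss_tes <- function(genes) {
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  genes$tss <- ifelse(plus, BiocGenerics::start(genes),
                      BiocGenerics::end(genes))
  genes$tes <- ifelse(plus, BiocGenerics::end(genes),
                      BiocGenerics::start(genes))
  genes
}

set_chrom_sizes <- function(gr, sizes) {
  missing <- setdiff(GenomeInfoDb::seqlevels(gr), names(sizes))
  if (length(missing))
    pg_stop("chromosome(s) absent from sizes: %s",
            paste(missing, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- sizes
  bad <- BiocGenerics::end(gr) >
    GenomeInfoDb::seqlengths(gr)[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(bad))
    pg_stop("gene(s) extend past chromosome end: %s",
            paste(gr$gene_id[bad], collapse = ", "))
  gr
}

# Deterministic order: chrom, start, gene_id.
sort_genes <- function(genes) {
  ord <- order(as.character(GenomeInfoDb::seqnames(genes)),
               BiocGenerics::start(genes), genes$gene_id)
  genes[ord]
}

#' Write a gene model back to GTF
#'
#' @param genes `GRanges` from [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(genes, path) {
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::ranges(genes),
                                strand = BiocGenerics::strand(genes))
  out$source <- "peakgain"
  out$type <- "gene"
  out$gene_id <- genes$gene_id
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Promoter (TSS) windows for a gene model
#'
#' A strand-aware window around each TSS covering `upstream` bp 5' of the TSS
#' through `downstream` bp 3' of it, both ends inclusive (so the default
#' +/- 2 kb window is 4001 bp wide). Windows are clipped to chromosome
#' bounds when `seqlengths` are set.
#'
#' @param genes `GRanges` from [read_annotation()].
#' @param upstream,downstream Non-negative extents in bp; default 2000 each.
#' @return `GRanges` of TSS windows, one per gene, named by `gene_id`.
#' @export
promoter_regions <- function(genes, upstream = 2000, downstream = 2000) {
  if (upstream < 0 || downstream < 0)
    pg_stop("upstream/downstream must be >= 0")
  prom <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = upstream,
                             downstream = downstream + 1))
  prom <- clip_to_chrom(prom)
  gone <- BiocGenerics::width(prom) < 1
  if (any(gone))
    pg_stop("promoter window entirely off-chromosome for: %s",
            paste(genes$gene_id[gone], collapse = ", "))
  names(prom) <- prom$gene_id
  prom
}

# Clip ranges to [1, seqlength]; fully off-chromosome ranges become zero-width.
clip_to_chrom <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)[as.character(GenomeInfoDb::seqnames(gr))]
  new_start <- pmax(BiocGenerics::start(gr), 1L)
  has_len <- !is.na(sl)
  new_end <- BiocGenerics::end(gr)
  new_end[has_len] <- pmin(new_end[has_len], sl[has_len])
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(new_start,
                                           pmax(new_end, new_start - 1L))
  out
}

#' Gene-body regions with a TSS-proximal exclusion
#'
#' The transcribed span of each gene minus the first `tss_exclusion` bp
#' downstream of the TSS (inclusive of the TSS itself), so that TSS-window and
#' gene-body change calls are disjoint by construction when `tss_exclusion`
#' equals the promoter's downstream extent. The excluded span matches the
#' inclusive promoter window: positions 0..`tss_exclusion` bp downstream of
#' the TSS. Genes too short to retain any body are dropped;
#' `tss_exclusion = 0` restores the full gene span.
#'
#' @param genes `GRanges` from [read_annotation()].
#' @param tss_exclusion Excluded span in bp downstream of (and including) the
#'   TSS; default 2000.
#' @return `GRanges` of gene-body regions named by `gene_id`; genes with no
#'   remaining body are omitted.
#' @export
gene_body_regions <- function(genes, tss_exclusion = 2000) {
  if (tss_exclusion < 0) pg_stop("tss_exclusion must be >= 0")
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  s <- BiocGenerics::start(genes)
  e <- BiocGenerics::end(genes)
  off <- if (tss_exclusion == 0) 0L else as.integer(tss_exclusion) + 1L
  body_start <- ifelse(plus, s + off, s)
  body_end <- ifelse(plus, e, e - off)
  keep <- body_end >= body_start
  out <- genes[keep]
  IRanges::ranges(out) <- IRanges::IRanges(body_start[keep], body_end[keep])
  names(out) <- out$gene_id
  out
}

#' Strand-aware downstream windows (past the TES)
#'
#' @param genes `GRanges` from [read_annotation()].
#' @param window Window length in bp past the TES; default 3000.
#' @return `GRanges` of downstream windows named by `gene_id`; genes whose
#'   window falls entirely off-chromosome are omitted.
#' @export
downstream_regions <- function(genes, window = 3000) {
  if (window < 1) pg_stop("window must be >= 1")
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  s <- BiocGenerics::start(genes)
  e <- BiocGenerics::end(genes)
  d_start <- ifelse(plus, e + 1, s - window)
  d_end <- ifelse(plus, e + window, s - 1)
  out <- genes
  IRanges::ranges(out) <- IRanges::IRanges(pmax(d_start, 1L),
                                           pmax(d_end, pmax(d_start, 1L)))
  out <- clip_to_chrom(out)
  keep <- BiocGenerics::width(out) >= 1 & d_end >= 1
  out <- out[keep]
  names(out) <- out$gene_id
  out
}
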