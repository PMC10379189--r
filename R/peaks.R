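#' Read a peak set from BED6 or ENCODE narrowPeak
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' `GRanges` convention. For narrowPeak input, column 10 is the summit offset
#' from the peak start; the ENCODE sentinel `-1` means "no summit".
#'
#' @param path Path to a BED3+/BED6/narrowPeak file.
#' @param condition_label Label attached to the set (e.g. `"treatment"`).
#' @return A `GRanges` sorted by (chrom, start, end) with metadata columns
#'   `name`, `score`, `summit_offset` and the condition label stored in
#'   `metadata()$condition_label`. Exact duplicate intervals are dropped with
#'   a warning.
#' @export
read_peaks <- function(path, condition_label = "") {
  if (!file.exists(path)) pg_stop("peak file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) pg_stop("peak file needs >= 3 columns: %s", path)
  start0 <- as.numeric(df[[2]])
  end0 <- as.numeric(df[[3]])
  bad <- which(!(end0 > start0) | start0 < 0 | is.na(start0) | is.na(end0))
  if (length(bad))
    pg_stop("invalid peak interval at line %d of %s (need 0 <= start < end)",
            bad[1], path)
  n <- nrow(df)
  name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("%s_peak_%d", condition_label, seq_len(n))
  score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else
    rep(NA_real_, n)
  summit <- rep(NA_integer_, n)
  if (ncol(df) >= 10) {
    raw <- suppressWarnings(as.integer(df[[10]]))
    width <- end0 - start0
    oob <- which(!is.na(raw) & raw != -1L & (raw < 0 | raw >= width))
    if (length(oob))
      pg_stop("summit offset out of range at line %d of %s", oob[1], path)
    summit <- ifelse(!is.na(raw) & raw >= 0, raw, NA_integer_)
  }
  gr <- GenomicRanges::GRanges(as.character(df[[1]]),
                               IRanges::IRanges(start0 + 1, end0))
  gr$name <- name
  gr$score <- score
  gr$summit_offset <- summit
  gr <- sort_peaks(gr)
  dup <- duplicated(paste(GenomeInfoDb::seqnames(gr),
                          BiocGenerics::start(gr), BiocGenerics::end(gr)))
  if (any(dup)) {
    warning(sprintf("dropping %d exact duplicate interval(s) in %s",
                    sum(dup), path))
    gr <- gr[!dup]
  }
  S4Vectors::metadata(gr)$condition_label <- condition_label
  gr
}

sort_peaks <- function(gr) {
  gr[order(as.character(GenomeInfoDb::seqnames(gr)),
           BiocGenerics::start(gr), BiocGenerics::end(gr))]
}

#' Write a peak set as BED6 (or narrowPeak when summits are present)
#'
#' @param peaks `GRanges` from [read_peaks()] or the synthetic generator.
#' @param path Output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                   start = BiocGenerics::start(peaks) - 1L,
                   end = BiocGenerics::end(peaks),
                   name = if (is.null(peaks$name))
                     sprintf("peak_%d", seq_along(peaks)) else peaks$name,
                   score = ifelse(is.na(peaks$score), 0, peaks$score),
                   strand = ".")
  if (format == "narrowPeak") {
    so <- if (is.null(peaks$summit_offset)) rep(NA_integer_, length(peaks))
          else peaks$summit_offset
    df$signalValue <- 0
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- ifelse(is.na(so), -1L, so)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise minimum-overlap test
#'
#' Element-wise test of whether intervals `a[i]` and `b[i]` share at least
#' `min_overlap` bp on the same chromosome. Strand is ignored.
#'
#' @param a,b `GRanges` of equal length (or one of length 1, recycled).
#' @param min_overlap Minimum shared bases, default 1.
#' @return Logical vector.
#' @export
overlaps_at_least <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) pg_stop("min_overlap must be >= 1")
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  ov <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1
  same & ov >= min_overlap
}

#' Partition two peak sets into common and condition-specific peaks
#'
#' A peak of set A is *common* iff it overlaps (by at least `min_overlap` bp)
#' at least one peak of set B, otherwise it is *specific* to A; symmetrically
#' for B. Each input peak appears in exactly one output set, so no merged
#' peak universe is constructed and `|common_a| + |specific_a| == |A|`.
#'
#' @param set_a,set_b Peak `GRanges` (see [read_peaks()]); `set_a` is
#'   conventionally the treatment, `set_b` the control.
#' @param min_overlap Minimum shared bases for two peaks to count as
#'   overlapping, default 1.
#' @return An object of class `PeakPartition`: a list with `GRanges`
#'   components `common_a`, `specific_a`, `common_b`, `specific_b` and the
#'   two condition labels.
#' @export
partition_peaks <- function(set_a, set_b, min_overlap = 1) {
  if (min_overlap < 1) pg_stop("min_overlap must be >= 1")
  hit_a <- GenomicRanges::countOverlaps(set_a, set_b,
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE) > 0
  hit_b <- GenomicRanges::countOverlaps(set_b, set_a,
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE) > 0
  structure(list(common_a = set_a[hit_a], specific_a = set_a[!hit_a],
                 common_b = set_b[hit_b], specific_b = set_b[!hit_b],
                 label_a = S4Vectors::metadata(set_a)$condition_label,
                 label_b = S4Vectors::metadata(set_b)$condition_label,
                 min_overlap = min_overlap),
            class = "PeakPartition")
}

#' @export
print.PeakPartition <- function(x, ...) {
  cat(sprintf("PeakPartition (>= %d bp overlap)\n", x$min_overlap))
  cat(sprintf("  %s: %d peaks (%d common, %d specific)\n",
              if (is.null(x$label_a)) "A" else x$label_a,
              length(x$common_a) + length(x$specific_a),
              length(x$common_a), length(x$specific_a)))
  cat(sprintf("  %s: %d peaks (%d common, %d specific)\n",
              if (is.null(x$label_b)) "B" else x$label_b,
              length(x$common_b) + length(x$specific_b),
              length(x$common_b), length(x$specific_b)))
  invisible(x)
}

# The genomic position used to classify/locate a peak: summit when present,
# else the midpoint (integer division).
peak_test_points <- function(peaks, use_summit = TRUE) {
  mid <- (BiocGenerics::start(peaks) + BiocGenerics::end(peaks)) %/% 2L
  if (use_summit && !is.null(peaks$summit_offset)) {
    pos <- ifelse(is.na(peaks$summit_offset), mid,
                  BiocGenerics::start(peaks) + peaks$summit_offset)
  } else pos <- mid
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                         IRanges::IRanges(pos, pos))
}

#' Annotate peaks to genomic features with fixed precedence
#'
#' Each peak is assigned one feature class by the precedence
#' Promoter > Exon > Intron > Downstream > DistalIntergenic. The overlap test
#' uses the summit position when present, else the full peak interval
#' (`use_summit = FALSE` forces full-interval testing throughout). When no
#' exon ranges are supplied, each gene is treated as a single exon spanning
#' its whole interval, so the Intron class cannot occur. The nearest gene is
#' the one minimising the absolute distance from the peak's summit (or
#' midpoint) to its TSS, with ties broken by lexicographically smaller
#' `gene_id`; the reported distance is signed, negative when the peak lies
#' upstream of the TSS in the gene's orientation.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene `GRanges` from [read_annotation()].
#' @param exons Optional `GRanges` of exons; default synthesises one exon per
#'   gene.
#' @param promoter_up,promoter_down Promoter window extents in bp
#'   (default 2000/2000).
#' @param downstream_window Downstream window past the TES in bp
#'   (default 3000).
#' @param use_summit Use the summit as the overlap test point when available
#'   (default `TRUE`).
#' @return A `data.frame` with one row per peak: `name`, `chrom`, `start`,
#'   `end` (0-based half-open, as in BED), `feature`, `nearest_gene_id`,
#'   `distance_bp`.
#' @export
annotate_peaks <- function(peaks, genes, exons = NULL,
                           promoter_up = 2000, promoter_down = 2000,
                           downstream_window = 3000, use_summit = TRUE) {
  if (length(genes) == 0) pg_stop("empty annotation")
  if (length(peaks) == 0) pg_stop("empty peak set")
  prom <- promoter_regions(genes, promoter_up, promoter_down)
  if (is.null(exons)) exons <- genes
  introns <- GenomicRanges::setdiff(
    GenomicRanges::reduce(genes, ignore.strand = TRUE),
    GenomicRanges::reduce(exons, ignore.strand = TRUE), ignore.strand = TRUE)
  downs <- downstream_regions(genes, downstream_window)

  has_summit <- if (is.null(peaks$summit_offset)) rep(FALSE, length(peaks))
                else !is.na(peaks$summit_offset)
  test <- GenomicRanges::granges(peaks)
  if (use_summit && any(has_summit)) {
    pts <- peak_test_points(peaks, use_summit = TRUE)
    test[has_summit] <- pts[has_summit]
  }

  in_class <- function(regions) {
    GenomicRanges::countOverlaps(test, regions, ignore.strand = TRUE) > 0
  }
  feature <- rep("DistalIntergenic", length(peaks))
  feature[in_class(downs)] <- "Downstream"
  feature[in_class(introns)] <- "Intron"
  feature[in_class(exons)] <- "Exon"
  feature[in_class(prom)] <- "Promoter"

  # nearest TSS from the summit/midpoint, per chromosome
  pts <- BiocGenerics::start(peak_test_points(peaks, use_summit = use_summit))
  pk_chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  g_chrom <- as.character(GenomeInfoDb::seqnames(genes))
  g_plus <- as.character(BiocGenerics::strand(genes)) == "+"
  nearest_id <- rep(NA_character_, length(peaks))
  distance_bp <- rep(NA_integer_, length(peaks))
  for (chr in unique(pk_chrom)) {
    gi <- which(g_chrom == chr)
    if (!length(gi)) next
    pi <- which(pk_chrom == chr)
    tss <- genes$tss[gi]
    for (j in pi) {
      d_gen <- pts[j] - tss
      d_signed <- ifelse(g_plus[gi], d_gen, -d_gen)
      ord <- order(abs(d_signed), genes$gene_id[gi])
      nearest_id[j] <- genes$gene_id[gi][ord[1]]
      distance_bp[j] <- d_signed[ord[1]]
    }
  }
  data.frame(name = if (is.null(peaks$name))
               sprintf("peak_%d", seq_along(peaks)) else peaks$name,
             chrom = pk_chrom,
             start = BiocGenerics::start(peaks) - 1L,
             end = BiocGenerics::end(peaks),
             feature = feature,
             nearest_gene_id = nearest_id,
             distance_bp = distance_bp,
             stringsAsFactors = FALSE)
}

#' Feature-class distribution of annotated peaks
#'
#' @param annotated `data.frame` from [annotate_peaks()].
#' @return `data.frame` with columns `feature`, `count`, `fraction`
#'   (fractions sum to 1).
#' @export
feature_distribution <- function(annotated) {
  if (is.null(annotated$feature) || nrow(annotated) == 0)
    pg_stop("no annotated peaks")
  counts <- table(annotated$feature)
  data.frame(feature = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Genes within a distance bound of any peak
#'
#' A gene is included iff the edge-to-edge gap between its interval and some
#' peak interval is at most `max_distance` bp (an overlap counts as gap 0).
#' This is the association rule used to link differential peaks to genes
#' within 20 kb.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene `GRanges`.
#' @param max_distance Maximum allowed gap in bp, default 20000.
#' @return Sorted character vector of gene ids.
#' @export
genes_near_peaks <- function(peaks, genes, max_distance = 20000) {
  if (max_distance < 0) pg_stop("max_distance must be >= 0")
  hits <- GenomicRanges::findOverlaps(genes, peaks, maxgap = max_distance,
                                      ignore.strand = TRUE)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}
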