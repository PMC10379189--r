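#' Read binned coverage from a bedGraph file
#'
#' bedGraph intervals are length-weighted into fixed-width bins per
#' chromosome; bases not covered by any record contribute 0. Overlapping
#' bedGraph records are rejected because the signal value at the shared bases
#' would be ambiguous.
#'
#' @param path Path to a bedGraph file (0-based half-open records).
#' @param chrom_sizes Named vector of chromosome lengths (or path to a
#'   two-column TSV).
#' @param bin_size Bin width in bp, default 50.
#' @param condition_label Label attached to the track.
#' @return An object of class `SignalTrack`: list with `condition_label`,
#'   `bin_size`, `chrom_sizes`, and `values`, a named list with one numeric
#'   vector of per-bin mean coverage per chromosome (length
#'   `ceiling(len / bin_size)`).
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 50,
                          condition_label = "") {
  if (!file.exists(path)) pg_stop("bedGraph file not found: %s", path)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (bin_size < 1) pg_stop("bin_size must be >= 1")
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    missing <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                       names(chrom_sizes))
    if (length(missing))
      pg_stop("bedGraph chromosome(s) not in sizes: %s",
              paste(missing, collapse = ", "))
    oob <- BiocGenerics::end(gr) >
      chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))] |
      BiocGenerics::start(gr) < 1
    if (any(oob)) pg_stop("bedGraph record outside chromosome bounds")
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    if (sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(gr)))
      pg_stop("overlapping bedGraph records in %s (ambiguous signal)", path)
  }
  values <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    n_bins <- ceiling(len / bin_size)
    sub <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chr]
    w <- if (length(sub)) as.numeric(sub$score) else numeric(0)
    cov <- IRanges::coverage(IRanges::ranges(sub), weight = w, width = len)
    starts <- seq.int(1L, by = bin_size, length.out = n_bins)
    ends <- pmin(starts + bin_size - 1L, len)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov,
                                                 start = starts, end = ends)))
  })
  names(values) <- names(chrom_sizes)
  signal_track(values, bin_size, chrom_sizes, condition_label)
}

#' Construct a SignalTrack from per-chromosome bin vectors
#'
#' @param values Named list of numeric per-bin coverage vectors.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param condition_label Label for the track.
#' @return A `SignalTrack`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes,
                         condition_label = "") {
  if (!is.list(values) || is.null(names(values)))
    pg_stop("values must be a named list of numeric vectors")
  for (chr in names(values)) {
    expected <- ceiling(chrom_sizes[[chr]] / bin_size)
    if (length(values[[chr]]) != expected)
      pg_stop("track for %s has %d bins, expected %d",
              chr, length(values[[chr]]), expected)
    if (any(values[[chr]] < 0)) pg_stop("coverage values must be >= 0")
  }
  structure(list(condition_label = condition_label,
                 bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes,
                 values = values),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack '%s': %d chromosome(s), bin %d bp\n",
              x$condition_label, length(x$values), x$bin_size))
  invisible(x)
}

# Per-base signal over 1-based positions; positions outside the chromosome
# return 0 (used for window padding).
track_values_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) pg_stop("unknown chromosome: %s", chrom)
  len <- track$chrom_sizes[[chrom]]
  out <- numeric(length(pos))
  ok <- pos >= 1 & pos <= len
  out[ok] <- v[(pos[ok] - 1L) %/% track$bin_size + 1L]
  out
}

#' Base-pair-weighted mean coverage over a region
#'
#' @param track A `SignalTrack`.
#' @param region A length-1 `GRanges` (must lie within its chromosome).
#' @return Mean per-base coverage (numeric scalar).
#' @export
region_mean_signal <- function(track, region) {
  if (length(region) != 1) pg_stop("region must be a single range")
  chrom <- as.character(GenomeInfoDb::seqnames(region))
  s <- BiocGenerics::start(region)
  e <- BiocGenerics::end(region)
  len <- track$chrom_sizes[[chrom]]
  if (is.null(len)) pg_stop("unknown chromosome: %s", chrom)
  if (s < 1 || e > len) pg_stop("region outside chromosome bounds")
  mean(track_values_at(track, chrom, s:e))
}

#' Metagene matrix of signal around TSS or TES anchors
#'
#' For each gene, extracts `2 * flank / bin_size` bins of coverage centred on
#' the anchor, oriented 5' to 3' (rows of `-` strand genes are reversed).
#' Windows that run past a chromosome edge are zero-padded and flagged.
#'
#' @param track A `SignalTrack`.
#' @param genes Gene `GRanges` from [read_annotation()].
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank Half-window in bp (must be a multiple of `bin_size`),
#'   default 3000.
#' @return An object of class `ProfileMatrix`: list with `anchor`, `flank`,
#'   `bin_size`, `n_bins`, `rows` (gene x bin matrix, rownames = gene ids),
#'   `mean_profile` (column means) and `out_of_bounds` (logical per gene).
#' @export
anchored_profile <- function(track, genes, anchor = c("TSS", "TES"),
                             flank = 3000) {
  anchor <- match.arg(anchor)
  if (length(genes) == 0) pg_stop("no genes")
  if (flank %% track$bin_size != 0)
    pg_stop("flank must be a multiple of bin_size")
  n_bins <- as.integer(2 * flank / track$bin_size)
  pos <- if (anchor == "TSS") genes$tss else genes$tes
  chroms <- as.character(GenomeInfoDb::seqnames(genes))
  minus <- as.character(BiocGenerics::strand(genes)) == "-"
  rows <- matrix(0, nrow = length(genes), ncol = n_bins,
                 dimnames = list(genes$gene_id, NULL))
  oob <- logical(length(genes))
  for (i in seq_along(genes)) {
    window <- (pos[i] - flank):(pos[i] + flank - 1L)
    len <- track$chrom_sizes[[chroms[i]]]
    oob[i] <- window[1] < 1 || window[length(window)] > len
    vals <- track_values_at(track, chroms[i], window)
    bins <- colMeans(matrix(vals, nrow = track$bin_size))
    if (minus[i]) bins <- rev(bins)
    rows[i, ] <- bins
  }
  structure(list(anchor = anchor, flank = flank, bin_size = track$bin_size,
                 n_bins = n_bins, rows = rows,
                 mean_profile = colMeans(rows), out_of_bounds = oob,
                 condition_label = track$condition_label),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix '%s': %d genes x %d bins around %s (+/- %d bp)\n",
              x$condition_label, nrow(x$rows), x$n_bins, x$anchor, x$flank))
  invisible(x)
}

#' Write a profile matrix (and its mean profile) as TSV
#'
#' @param pm A `ProfileMatrix`.
#' @param path Output TSV path for the per-gene matrix.
#' @param mean_path Optional output path for the mean profile.
#' @export
write_profile_matrix <- function(pm, path, mean_path = NULL) {
  df <- data.frame(gene_id = rownames(pm$rows), pm$rows, check.names = FALSE)
  colnames(df)[-1] <- sprintf("bin_%d", seq_len(pm$n_bins))
  write_tsv(df, path)
  if (!is.null(mean_path)) {
    offset <- (seq_len(pm$n_bins) - 1L) * pm$bin_size - pm$flank
    write_tsv(data.frame(bin_start_offset = offset, mean = pm$mean_profile),
              mean_path)
  }
  invisible(path)
}

#' Plot one or more mean profiles around an anchor
#'
#' @param ... `ProfileMatrix` objects (lines are labelled by condition).
#' @param main Plot title.
#' @importFrom graphics lines legend plot
#' @export
plot_profile <- function(..., main = "Mean signal profile") {
  pms <- list(...)
  offsets <- lapply(pms, function(p)
    (seq_len(p$n_bins) - 0.5) * p$bin_size - p$flank)
  ylim <- range(unlist(lapply(pms, `[[`, "mean_profile")))
  plot(offsets[[1]], pms[[1]]$mean_profile, type = "l", col = 1,
       xlab = sprintf("bp from %s", pms[[1]]$anchor), ylab = "mean coverage",
       ylim = ylim, main = main)
  if (length(pms) > 1)
    for (i in 2:length(pms))
      lines(offsets[[i]], pms[[i]]$mean_profile, col = i)
  legend("topright", lty = 1, col = seq_along(pms),
         legend = vapply(pms, `[[`, "", "condition_label"), bty = "n")
  invisible(NULL)
}
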