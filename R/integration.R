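#' Read a gene-level expression table
#'
#' Expects a TSV with columns `gene_id`, `mean_treatment`, `mean_control`
#' and optionally `qvalue`. Records where both means are zero are dropped
#' (no usable signal).
#'
#' @param path Path to the TSV.
#' @return `data.frame` of retained records.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) pg_stop("expression file not found: %s", path)
  df <- read_tsv(path)
  need <- c("gene_id", "mean_treatment", "mean_control")
  if (!all(need %in% names(df)))
    pg_stop("expression table needs columns: %s", paste(need, collapse = ", "))
  if (any(df$mean_treatment < 0 | df$mean_control < 0))
    pg_stop("expression means must be >= 0")
  df[df$mean_treatment > 0 | df$mean_control > 0, , drop = FALSE]
}

#' Call differentially expressed genes by fold change
#'
#' A gene is *up* iff
#' `(mean_treatment + pseudocount) / (mean_control + pseudocount)` is at
#' least `fold_threshold` and *down* iff the ratio is at most
#' `1 / fold_threshold`; both boundaries are inclusive. With
#' `pseudocount = 0`, a gene with zero control mean is called up when its
#' treatment mean is positive and excluded otherwise.
#'
#' @param records Expression `data.frame` (see [read_expression()]).
#' @param fold_threshold Fold-change threshold (> 1), default 1.25.
#' @param pseudocount Added to both means before forming the ratio,
#'   default 0.
#' @param max_qvalue Optional: additionally require `qvalue <= max_qvalue`
#'   (needs a `qvalue` column).
#' @return An object of class `DEGSet`: list with sorted character sets `up`
#'   and `down` and the threshold used.
#' @export
call_degs <- function(records, fold_threshold = 1.25, pseudocount = 0,
                      max_qvalue = NULL) {
  if (fold_threshold <= 1) pg_stop("fold_threshold must be > 1")
  num <- records$mean_treatment + pseudocount
  den <- records$mean_control + pseudocount
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  up <- !is.na(ratio) & ratio >= fold_threshold
  down <- !is.na(ratio) & ratio <= 1 / fold_threshold
  if (!is.null(max_qvalue)) {
    if (is.null(records$qvalue))
      pg_stop("max_qvalue given but no qvalue column")
    pass <- !is.na(records$qvalue) & records$qvalue <= max_qvalue
    up <- up & pass
    down <- down & pass
  }
  structure(list(up = sort(unique(records$gene_id[up])),
                 down = sort(unique(records$gene_id[down])),
                 fold_threshold = fold_threshold),
            class = "DEGSet")
}

#' @export
print.DEGSet <- function(x, ...) {
  cat(sprintf("DEGSet at fold >= %.3g: %d up, %d down\n",
              x$fold_threshold, length(x$up), length(x$down)))
  invisible(x)
}

#' Per-gene gained/lost signal calls in TSS and gene-body regions
#'
#' A gene is called (`region`, `gained`) when at least one treatment-specific
#' peak overlaps (>= 1 bp) that region, and (`region`, `lost`) when at least
#' one control-specific peak does. Regions are the inclusive TSS window
#' (`tss_up`/`tss_down` around the TSS) and the gene body minus its
#' TSS-proximal exclusion, so the two region calls cannot share evidence
#' bases. A gene may carry several calls (both regions; gained and lost) —
#' calls are reported, not collapsed.
#'
#' @param partition A `PeakPartition` from [partition_peaks()] with set A the
#'   treatment and set B the control.
#' @param genes Gene `GRanges` from [read_annotation()].
#' @param tss_up,tss_down TSS window extents in bp (default 2000/2000).
#' @param tss_exclusion Gene-body exclusion span in bp (default 2000).
#' @return `data.frame` with columns `gene_id`, `region`
#'   (`"TSS"`/`"gene_body"`), `direction` (`"gained"`/`"lost"`) and the list
#'   column `evidence_peaks` (peak names supporting the call); one row per
#'   unique (gene, region, direction), sorted.
#' @export
classify_region_changes <- function(partition, genes, tss_up = 2000,
                                    tss_down = 2000, tss_exclusion = 2000) {
  if (!inherits(partition, "PeakPartition"))
    pg_stop("partition must be a PeakPartition")
  regions <- list(TSS = promoter_regions(genes, tss_up, tss_down),
                  gene_body = gene_body_regions(genes, tss_exclusion))
  sources <- list(gained = partition$specific_a,
                  lost = partition$specific_b)
  rows <- list()
  for (region in names(regions)) {
    reg <- regions[[region]]
    for (direction in names(sources)) {
      pk <- sources[[direction]]
      if (length(pk) == 0 || length(reg) == 0) next
      hits <- GenomicRanges::findOverlaps(reg, pk, ignore.strand = TRUE)
      if (!length(hits)) next
      gid <- reg$gene_id[S4Vectors::queryHits(hits)]
      ev <- pk$name[S4Vectors::subjectHits(hits)]
      for (g in unique(gid)) {
        rows[[length(rows) + 1L]] <- list(
          gene_id = g, region = region, direction = direction,
          evidence_peaks = sort(unique(ev[gid == g])))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), region = character(),
                      direction = character(),
                      evidence_peaks = I(list()),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                   region = vapply(rows, `[[`, "", "region"),
                   direction = vapply(rows, `[[`, "", "direction"),
                   stringsAsFactors = FALSE)
  df$evidence_peaks <- I(lapply(rows, `[[`, "evidence_peaks"))
  df <- df[order(df$gene_id, df$region, df$direction), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write region-change calls as TSV (evidence peaks comma-joined)
#'
#' @param changes `data.frame` from [classify_region_changes()].
#' @param path Output path.
#' @export
write_region_changes <- function(changes, path) {
  out <- changes
  out$evidence_peaks <- vapply(changes$evidence_peaks, paste,
                               "", collapse = ",")
  write_tsv(out, path)
}

#' Intersect region-change calls with differential expression
#'
#' Reproduces the two-way and quadrant intersections of a peak/expression
#' integration: `common_genes` is the distance-associated differential-peak
#' gene set intersected with all DEGs; `both_down` the common genes carrying
#' a lost call (either region) that are down-regulated; `quadrants` the
#' common genes split by (region, gained/lost, up/down).
#'
#' @param changes `data.frame` from [classify_region_changes()].
#' @param degs A `DEGSet` from [call_degs()].
#' @param diff_peak_genes Character vector of gene ids associated with
#'   condition-specific peaks (see [genes_near_peaks()]).
#' @return An object of class `IntegrationResult`: list with sorted sets
#'   `common_genes`, `both_down`, a named list `quadrants` (keys like
#'   `"TSS_lost_down"`), and a `counts` data.frame.
#' @export
integrate_changes <- function(changes, degs, diff_peak_genes) {
  if (!inherits(degs, "DEGSet")) pg_stop("degs must be a DEGSet")
  all_degs <- union(degs$up, degs$down)
  common <- sort(intersect(diff_peak_genes, all_degs))
  lost_genes <- unique(changes$gene_id[changes$direction == "lost"])
  both_down <- sort(intersect(intersect(common, lost_genes), degs$down))
  quadrants <- list()
  for (region in c("TSS", "gene_body")) {
    for (direction in c("gained", "lost")) {
      called <- unique(changes$gene_id[changes$region == region &
                                         changes$direction == direction])
      for (sign in c("up", "down")) {
        key <- paste(region, direction, sign, sep = "_")
        quadrants[[key]] <- sort(intersect(intersect(common, called),
                                           degs[[sign]]))
      }
    }
  }
  counts <- data.frame(set = c("diff_peak_genes", "degs_up", "degs_down",
                               "common_genes", "both_down", names(quadrants)),
                       n = c(length(diff_peak_genes), length(degs$up),
                             length(degs$down), length(common),
                             length(both_down),
                             vapply(quadrants, length, 0L)),
                       stringsAsFactors = FALSE)
  structure(list(common_genes = common, both_down = both_down,
                 quadrants = quadrants, counts = counts),
            class = "IntegrationResult")
}

#' @export
print.IntegrationResult <- function(x, ...) {
  cat("IntegrationResult\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-22s %d\n", x$counts$set[i], x$counts$n[i]))
  invisible(x)
}

#' Serialise an IntegrationResult (all sets and counts) to JSON
#'
#' @param result An `IntegrationResult`.
#' @param path Output path.
#' @export
write_integration <- function(result, path) {
  jsonlite::write_json(list(common_genes = result$common_genes,
                            both_down = result$both_down,
                            quadrants = result$quadrants,
                            counts = result$counts),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
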