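#' Design of a synthetic two-condition ChIP/expression experiment
#'
#' Fixes every knob of the miniature experiment the generator emits: genome
#' layout, numbers of genes planted with condition-specific peaks in TSS
#' windows or gene bodies, numbers of up/down differentially expressed
#' genes, the planted expression folds, and noise. Defaults describe a
#' 2-chromosome, 50-gene genome with 5 lost-at-TSS, 3 gained-at-TSS and 4
#' lost-in-body genes, 10 down- and 6 up-regulated genes at folds 0.5/2.0,
#' every region-change gene carrying the matching expression change
#' (`overlap_with_changes = 1`), and no expression noise. Intergenic gaps
#' (>= 45 kb) keep every planted peak more than the 20 kb association bound
#' away from all other genes.
#'
#' @param n_chroms,chrom_length Genome layout (chromosomes x length bp).
#' @param n_genes Total genes.
#' @param gene_length Length-2 integer range of gene lengths in bp.
#' @param min_intergenic_gap Minimum gap between genes in bp.
#' @param n_lost_tss,n_gained_tss,n_lost_body,n_gained_body Planted
#'   region-change gene counts (disjoint gene sets).
#' @param n_up,n_down Planted DEG counts.
#' @param overlap_with_changes Fraction of region-change genes whose DEG
#'   sign matches the change direction (lost -> down, gained -> up).
#' @param background_peaks_per_condition Shared (common) peaks per condition.
#' @param fold_up,fold_down Planted expression ratios (treatment/control).
#' @param noise_sd Log-normal sd multiplied onto every expression mean.
#' @param baseline_expression Common expression baseline.
#' @param peak_width,peak_height,baseline_coverage Peak geometry and the
#'   flat coverage model (baseline + height under peaks).
#' @param tss_window,tss_exclusion,assoc_distance,fold_threshold The
#'   analysis parameters the truth table is defined against (TSS window
#'   half-width, gene-body exclusion, peak-gene association bound, DEG fold
#'   threshold).
#' @param seed RNG seed (integer).
#' @return A validated `SyntheticDesign` list.
#' @export
synthetic_design <- function(n_chroms = 2, chrom_length = 2e6, n_genes = 50,
                             gene_length = c(8000, 16000),
                             min_intergenic_gap = 45000,
                             n_lost_tss = 5, n_gained_tss = 3,
                             n_lost_body = 4, n_gained_body = 0,
                             n_up = 6, n_down = 10,
                             overlap_with_changes = 1.0,
                             background_peaks_per_condition = 20,
                             fold_up = 2.0, fold_down = 0.5, noise_sd = 0,
                             baseline_expression = 100,
                             peak_width = 400, peak_height = 9,
                             baseline_coverage = 1,
                             tss_window = 2000, tss_exclusion = 2000,
                             assoc_distance = 20000, fold_threshold = 1.25,
                             seed = 1) {
  d <- as.list(environment())
  n_changes <- n_lost_tss + n_gained_tss + n_lost_body + n_gained_body
  if (n_changes > n_genes) pg_stop("planted change counts exceed n_genes")
  if (n_up + n_down > n_genes) pg_stop("planted DEG counts exceed n_genes")
  if (overlap_with_changes < 0 || overlap_with_changes > 1)
    pg_stop("overlap_with_changes must be in [0, 1]")
  d$matched_lost <- round(overlap_with_changes * (n_lost_tss + n_lost_body))
  d$matched_gained <- round(overlap_with_changes *
                              (n_gained_tss + n_gained_body))
  if (d$matched_lost > n_down || d$matched_gained > n_up)
    pg_stop("overlap_with_changes demands more matched DEGs than n_down/n_up")
  free_needed <- (n_down - d$matched_lost) + (n_up - d$matched_gained)
  if (n_genes - n_changes < free_needed)
    pg_stop("not enough unplanted genes for the unmatched DEGs")
  if (fold_up < fold_threshold || fold_down > 1 / fold_threshold)
    pg_stop("planted folds must cross fold_threshold")
  if (gene_length[1] <= tss_exclusion)
    pg_stop("gene_length minimum must exceed tss_exclusion (bodies vanish)")
  if (min_intergenic_gap < assoc_distance + tss_window + 2 * peak_width)
    pg_stop("min_intergenic_gap too small to isolate planted peaks")
  class(d) <- "SyntheticDesign"
  d
}

# Random non-overlapping gene placement; errors before emission if the genes
# plus their gaps cannot fit.
place_genes <- function(d) {
  per_chrom <- rep(d$n_genes %/% d$n_chroms, d$n_chroms)
  extra <- d$n_genes %% d$n_chroms
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  rows <- list()
  gi <- 0L
  for (ci in seq_len(d$n_chroms)) {
    chrom <- sprintf("chr%d", ci)
    cursor <- d$min_intergenic_gap
    for (j in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      len <- sample(d$gene_length[1]:d$gene_length[2], 1)
      start <- cursor + 1L
      end <- start + len - 1L
      if (end + d$min_intergenic_gap > d$chrom_length)
        pg_stop("infeasible packing: %d genes do not fit on %d x %g bp",
                d$n_genes, d$n_chroms, d$chrom_length)
      strand <- sample(c("+", "-"), 1)
      rows[[gi]] <- data.frame(gene_id = sprintf("G%03d", gi), chrom = chrom,
                               start = start, end = end, strand = strand,
                               stringsAsFactors = FALSE)
      cursor <- end + d$min_intergenic_gap + sample(0:2000, 1)
    }
  }
  df <- do.call(rbind, rows)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df
}

# Assign planted roles: disjoint region-change groups, then DEG signs with
# the requested change/DEG concordance.
assign_roles <- function(d, gene_ids) {
  perm <- sample(gene_ids)
  take <- function(n) {
    if (n == 0) return(character(0))
    out <- perm[seq_len(n)]
    perm <<- perm[-seq_len(n)]
    out
  }
  roles <- list(lost_tss = take(d$n_lost_tss),
                gained_tss = take(d$n_gained_tss),
                lost_body = take(d$n_lost_body),
                gained_body = take(d$n_gained_body))
  lost <- c(roles$lost_tss, roles$lost_body)
  gained <- c(roles$gained_tss, roles$gained_body)
  down <- utils::head(lost, d$matched_lost)
  up <- utils::head(gained, d$matched_gained)
  down <- c(down, utils::head(perm, d$n_down - length(down)))
  perm <- setdiff(perm, down)
  up <- c(up, utils::head(perm, d$n_up - length(up)))
  roles$down <- down
  roles$up <- up
  roles
}

# Region intervals (1-based closed) the generator and the truth arithmetic
# share: inclusive TSS window and the body past the exclusion span.
truth_regions <- function(genes_df, d) {
  tssw <- data.frame(chrom = genes_df$chrom,
                     start = pmax(genes_df$tss - d$tss_window, 1),
                     end = genes_df$tss + d$tss_window,
                     gene_id = genes_df$gene_id, stringsAsFactors = FALSE)
  off <- d$tss_exclusion + 1
  plus <- genes_df$strand == "+"
  body <- data.frame(chrom = genes_df$chrom,
                     start = ifelse(plus, genes_df$start + off,
                                    genes_df$start),
                     end = ifelse(plus, genes_df$end,
                                  genes_df$end - off),
                     gene_id = genes_df$gene_id, stringsAsFactors = FALSE)
  body <- body[body$end >= body$start, , drop = FALSE]
  list(tss = tssw, body = body)
}

#' Generate a synthetic experiment bundle
#'
#' Emits, deterministically for a fixed seed, a complete miniature
#' experiment into `outdir`: a GTF of non-overlapping genes on both strands,
#' a chromosome-sizes TSV, two BED peak sets (shared background peaks that
#' mutually overlap between conditions, plus condition-specific peaks placed
#' inside the designated region of each planted gene and far from all other
#' genes), one bedGraph coverage track per condition (flat baseline with
#' elevated plateaus under that condition's peaks), an expression table with
#' the planted ratios under optional log-normal noise, a GMT term map whose
#' first term is exactly the planted lost-and-down gene set (plus decoys),
#' and a JSON truth table.
#'
#' @param design A `SyntheticDesign` from [synthetic_design()].
#' @param outdir Output directory (created if needed).
#' @return An object of class `SyntheticBundle`: list with `dir`, `files`
#'   (named paths), `design`, `genes` (placement table) and `truth`
#'   (planted labels and expected integration sets).
#' @export
generate_dataset <- function(design, outdir) {
  if (!inherits(design, "SyntheticDesign"))
    pg_stop("design must come from synthetic_design()")
  d <- design
  set.seed(d$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genes_df <- place_genes(d)
  roles <- assign_roles(d, genes_df$gene_id)
  regions <- truth_regions(genes_df, d)

  # --- condition-specific peaks centred in their target region ---
  centre_peak <- function(gene_id, region_df, name) {
    r <- region_df[region_df$gene_id == gene_id, ]
    centre <- (r$start + r$end) %/% 2
    data.frame(chrom = r$chrom, start = centre - d$peak_width %/% 2,
               end = centre + d$peak_width %/% 2 - 1,
               name = name, stringsAsFactors = FALSE)
  }
  specific <- list(treatment = list(), control = list())
  for (g in roles$gained_tss)
    specific$treatment[[length(specific$treatment) + 1]] <-
      centre_peak(g, regions$tss, sprintf("gained_TSS_%s", g))
  for (g in roles$gained_body)
    specific$treatment[[length(specific$treatment) + 1]] <-
      centre_peak(g, regions$body, sprintf("gained_body_%s", g))
  for (g in roles$lost_tss)
    specific$control[[length(specific$control) + 1]] <-
      centre_peak(g, regions$tss, sprintf("lost_TSS_%s", g))
  for (g in roles$lost_body)
    specific$control[[length(specific$control) + 1]] <-
      centre_peak(g, regions$body, sprintf("lost_body_%s", g))

  # --- shared background peaks at intergenic gap centres (common by a
  #     deliberate partial shift between the two conditions) ---
  gaps <- do.call(rbind, lapply(split(genes_df, genes_df$chrom), function(s) {
    s <- s[order(s$start), ]
    bounds <- c(0, s$end, d$chrom_length)
    starts <- utils::head(bounds, -1) + 1
    ends <- c(s$start - 1, d$chrom_length)
    data.frame(chrom = s$chrom[1], centre = (starts + ends) %/% 2)
  }))
  offsets <- c(-6000L, 0L, 6000L)
  cand <- data.frame(chrom = rep(gaps$chrom, each = length(offsets)),
                     centre = rep(gaps$centre, each = length(offsets)) +
                       rep(offsets, nrow(gaps)))
  if (d$background_peaks_per_condition > nrow(cand))
    pg_stop("too many background peaks for the available intergenic space")
  cand <- cand[sample(nrow(cand), d$background_peaks_per_condition), ,
               drop = FALSE]
  shift <- max(1L, d$peak_width %/% 4L)
  bg_a <- data.frame(chrom = cand$chrom,
                     start = cand$centre - d$peak_width %/% 2,
                     end = cand$centre + d$peak_width %/% 2 - 1,
                     name = sprintf("bg_%03d", seq_len(nrow(cand))),
                     stringsAsFactors = FALSE)
  bg_b <- bg_a
  bg_b$start <- bg_b$start + shift
  bg_b$end <- bg_b$end + shift

  to_gr <- function(lst, extra, label) {
    df <- rbind(do.call(rbind, c(lst, list(NULL))), extra)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    gr$name <- df$name
    gr$score <- rep(0, length(gr))
    gr$summit_offset <- rep(NA_integer_, length(gr))
    gr <- sort_peaks(gr)
    S4Vectors::metadata(gr)$condition_label <- label
    gr
  }
  peaks_a <- to_gr(specific$treatment, bg_a, "treatment")
  peaks_b <- to_gr(specific$control, bg_b, "control")

  # --- expression table ---
  ratio <- stats::runif(d$n_genes, 1 / 1.1, 1.1)
  names(ratio) <- genes_df$gene_id
  ratio[roles$up] <- d$fold_up
  ratio[roles$down] <- d$fold_down
  noise <- function(n) if (d$noise_sd > 0)
    exp(stats::rnorm(n, 0, d$noise_sd)) else rep(1, n)
  expr <- data.frame(gene_id = genes_df$gene_id,
                     mean_treatment = d$baseline_expression *
                       ratio[genes_df$gene_id] * noise(d$n_genes),
                     mean_control = d$baseline_expression * noise(d$n_genes),
                     stringsAsFactors = FALSE)

  # --- term map: planted term = lost-and-down genes, plus decoys ---
  planted_term <- sort(intersect(c(roles$lost_tss, roles$lost_body),
                                 roles$down))
  terms <- list()
  if (length(planted_term)) terms$planted_lost_down <- planted_term
  for (i in 1:6)
    terms[[sprintf("decoy_%d", i)]] <-
      sort(sample(genes_df$gene_id, min(8, d$n_genes)))

  # --- emit files ---
  chrom_sizes <- stats::setNames(rep(as.integer(d$chrom_length), d$n_chroms),
                                 sprintf("chr%d", seq_len(d$n_chroms)))
  files <- list(annotation = file.path(outdir, "genes.gtf"),
                chrom_sizes = file.path(outdir, "chrom_sizes.tsv"),
                peaks_treatment = file.path(outdir, "peaks_treatment.bed"),
                peaks_control = file.path(outdir, "peaks_control.bed"),
                track_treatment = file.path(outdir,
                                            "coverage_treatment.bedgraph"),
                track_control = file.path(outdir, "coverage_control.bedgraph"),
                expression = file.path(outdir, "expression.tsv"),
                terms = file.path(outdir, "terms.gmt"),
                truth = file.path(outdir, "truth.json"))
  genes_gr <- GenomicRanges::GRanges(genes_df$chrom,
                                     IRanges::IRanges(genes_df$start,
                                                      genes_df$end),
                                     strand = genes_df$strand)
  genes_gr$gene_id <- genes_df$gene_id
  write_annotation(genes_gr, files$annotation)
  write_chrom_sizes(chrom_sizes, files$chrom_sizes)
  write_peaks(peaks_a, files$peaks_treatment)
  write_peaks(peaks_b, files$peaks_control)
  write_coverage_for_peaks(peaks_a, chrom_sizes, d, files$track_treatment)
  write_coverage_for_peaks(peaks_b, chrom_sizes, d, files$track_control)
  write_tsv(expr, files$expression)
  write_term_map(terms, files$terms)

  bundle <- structure(list(dir = outdir, files = files, design = d,
                           genes = genes_df, roles = roles),
                      class = "SyntheticBundle")
  bundle$truth <- truth_from_files(bundle)
  jsonlite::write_json(bundle$truth, files$truth, auto_unbox = FALSE,
                       pretty = TRUE)
  bundle
}

# Flat coverage model: baseline everywhere, baseline + height under peaks.
write_coverage_for_peaks <- function(peaks, chrom_sizes, d, path) {
  cov <- IRanges::RleList(lapply(names(chrom_sizes), function(chr) {
    sub <- peaks[as.character(GenomeInfoDb::seqnames(peaks)) == chr]
    IRanges::coverage(IRanges::ranges(sub), width = chrom_sizes[[chr]]) *
      d$peak_height + d$baseline_coverage
  }))
  names(cov) <- names(chrom_sizes)
  gr <- as(cov, "GRanges")
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @export
print.SyntheticBundle <- function(x, ...) {
  cat(sprintf("SyntheticBundle in %s: %d genes, seed %d\n",
              x$dir, nrow(x$genes), x$design$seed))
  invisible(x)
}

# ---- truth arithmetic ------------------------------------------------------
# Recomputes the planted labels and expected integration sets directly from
# the emitted files with plain quadratic interval arithmetic (no package
# pipeline calls), so perturbations keep the truth table exact.

read_bed_df <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]] + 1, end = df[[3]],
             name = df[[4]], stringsAsFactors = FALSE)
}

# quadratic >=1 bp overlap flag of each a-row against any b-row
any_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) + 1 >= 1)
  }, TRUE)
}

truth_from_files <- function(bundle) {
  d <- bundle$design
  genes_df <- bundle$genes
  pa <- read_bed_df(bundle$files$peaks_treatment)
  pb <- read_bed_df(bundle$files$peaks_control)
  spec_a <- pa[!any_overlap(pa, pb), , drop = FALSE]
  spec_b <- pb[!any_overlap(pb, pa), , drop = FALSE]
  regions <- truth_regions(genes_df, d)

  genes_with_hit <- function(region_df, peaks_df) {
    unique(unlist(lapply(seq_len(nrow(peaks_df)), function(i) {
      hit <- region_df$chrom == peaks_df$chrom[i] &
        pmin(region_df$end, peaks_df$end[i]) -
        pmax(region_df$start, peaks_df$start[i]) + 1 >= 1
      region_df$gene_id[hit]
    })))
  }
  labels <- list(gained_tss = genes_with_hit(regions$tss, spec_a),
                 lost_tss = genes_with_hit(regions$tss, spec_b),
                 gained_body = genes_with_hit(regions$body, spec_a),
                 lost_body = genes_with_hit(regions$body, spec_b))

  # distance-bounded association of genes with any condition-specific peak
  spec_all <- rbind(spec_a, spec_b)
  assoc <- vapply(seq_len(nrow(genes_df)), function(i) {
    same <- spec_all$chrom == genes_df$chrom[i]
    if (!any(same)) return(FALSE)
    gap <- pmax(0, pmax(spec_all$start[same] - genes_df$end[i],
                        genes_df$start[i] - spec_all$end[same]) - 1)
    any(gap <= d$assoc_distance)
  }, TRUE)
  diff_peak_genes <- sort(genes_df$gene_id[assoc])

  expr <- read_tsv(bundle$files$expression)
  r <- expr$mean_treatment / expr$mean_control
  deg_up <- sort(expr$gene_id[r >= d$fold_threshold])
  deg_down <- sort(expr$gene_id[r <= 1 / d$fold_threshold])

  common <- sort(intersect(diff_peak_genes, union(deg_up, deg_down)))
  lost_any <- union(labels$lost_tss, labels$lost_body)
  quadrant <- function(lab, sign_set)
    sort(intersect(intersect(common, lab), sign_set))
  list(labels = labels,
       deg = list(up = deg_up, down = deg_down),
       diff_peak_genes = diff_peak_genes,
       expected = list(
         common_genes = common,
         both_down = sort(intersect(intersect(common, lost_any), deg_down)),
         quadrants = list(
           TSS_gained_up = quadrant(labels$gained_tss, deg_up),
           TSS_gained_down = quadrant(labels$gained_tss, deg_down),
           TSS_lost_up = quadrant(labels$lost_tss, deg_up),
           TSS_lost_down = quadrant(labels$lost_tss, deg_down),
           gene_body_gained_up = quadrant(labels$gained_body, deg_up),
           gene_body_gained_down = quadrant(labels$gained_body, deg_down),
           gene_body_lost_up = quadrant(labels$lost_body, deg_up),
           gene_body_lost_down = quadrant(labels$lost_body, deg_down))))
}

#' Apply a single controlled mutation to a synthetic bundle
#'
#' Mutates one emitted file in place and recomputes the truth table from the
#' mutated files, so negative-path tests can assert exactly which labels a
#' mutation removes or flips. Coverage tracks are regenerated after peak
#' mutations to stay consistent with the peak sets.
#'
#' @param bundle A `SyntheticBundle`.
#' @param op One of `"drop_peak"` (remove the named peak),
#'   `"shift_peak"` (translate it by `shift` bp) or `"flip_expression"`
#'   (swap the two means of the named gene).
#' @param target Peak name or gene id, depending on `op`.
#' @param shift Translation in bp for `shift_peak`, default 30000.
#' @return The updated bundle (files rewritten, truth recomputed).
#' @export
perturb_dataset <- function(bundle,
                            op = c("drop_peak", "shift_peak",
                                   "flip_expression"),
                            target, shift = 30000) {
  op <- match.arg(op)
  d <- bundle$design
  chrom_sizes <- read_chrom_sizes(bundle$files$chrom_sizes)
  if (op %in% c("drop_peak", "shift_peak")) {
    found <- FALSE
    for (side in c("peaks_treatment", "peaks_control")) {
      path <- bundle$files[[side]]
      pk <- read_peaks(path, sub("peaks_", "", side))
      hit <- which(pk$name == target)
      if (!length(hit)) next
      found <- TRUE
      if (op == "drop_peak") {
        pk <- pk[-hit]
      } else {
        moved <- GenomicRanges::shift(pk[hit], as.integer(shift))
        if (BiocGenerics::start(moved) < 1 ||
            BiocGenerics::end(moved) >
            chrom_sizes[[as.character(GenomeInfoDb::seqnames(moved))]])
          pg_stop("shift moves peak '%s' off the chromosome", target)
        pk[hit] <- moved
        pk <- sort_peaks(pk)
      }
      write_peaks(pk, path)
      track_path <- bundle$files[[sub("peaks", "track", side)]]
      write_coverage_for_peaks(pk, chrom_sizes, d, track_path)
    }
    if (!found) pg_stop("unknown peak: %s", target)
  } else {
    expr <- read_tsv(bundle$files$expression)
    hit <- which(expr$gene_id == target)
    if (!length(hit)) pg_stop("unknown gene: %s", target)
    tmp <- expr$mean_treatment[hit]
    expr$mean_treatment[hit] <- expr$mean_control[hit]
    expr$mean_control[hit] <- tmp
    write_tsv(expr, bundle$files$expression)
  }
  bundle$truth <- truth_from_files(bundle)
  jsonlite::write_json(bundle$truth, bundle$files$truth, auto_unbox = FALSE,
                       pretty = TRUE)
  bundle
}
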