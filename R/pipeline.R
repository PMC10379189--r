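#' Build a validated run configuration
#'
#' Collects the input paths and every analysis parameter of the end-to-end
#' pipeline, with the defaults used throughout: inclusive +/- 2 kb TSS
#' window, 3 kb downstream window, 20 kb peak-gene association bound,
#' 1.25-fold DEG threshold, 0.05 adjusted-p cutoff, 50 bp coverage bins and
#' a 2 kb gene-body TSS exclusion.
#'
#' @param annotation,peaks_treatment,peaks_control Input paths (required).
#' @param expression Expression table path (required for integration).
#' @param chrom_sizes Chromosome sizes TSV (required when coverage tracks
#'   are profiled).
#' @param track_treatment,track_control Optional bedGraph coverage paths.
#' @param terms Optional term-map path (GMT or TSV) for enrichment.
#' @param outdir Output directory.
#' @param promoter_up,promoter_down,downstream_window TSS/downstream window
#'   extents in bp.
#' @param max_distance Peak-gene association bound in bp.
#' @param fold_threshold,alpha DEG fold threshold and enrichment cutoff.
#' @param bin_size,tss_exclusion,profile_flank,min_overlap Coverage bin
#'   width, gene-body exclusion, profile half-window and minimum peak
#'   overlap, all in bp.
#' @param seed Seed recorded in the manifest and used for any sampling.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(annotation, peaks_treatment, peaks_control,
                       expression = NULL, chrom_sizes = NULL,
                       track_treatment = NULL, track_control = NULL,
                       terms = NULL, outdir = ".",
                       promoter_up = 2000, promoter_down = 2000,
                       downstream_window = 3000, max_distance = 20000,
                       fold_threshold = 1.25, alpha = 0.05, bin_size = 50,
                       tss_exclusion = 2000, profile_flank = 3000,
                       min_overlap = 1, seed = 1) {
  cfg <- as.list(environment())
  validate_run_config(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

validate_run_config <- function(cfg) {
  num <- c("promoter_up", "promoter_down", "downstream_window",
           "max_distance", "bin_size", "tss_exclusion", "profile_flank",
           "min_overlap")
  for (p in num)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      pg_stop("parameter %s must be a non-negative number", p)
  if (cfg$fold_threshold <= 1) pg_stop("fold_threshold must be > 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) pg_stop("alpha must be in (0, 1)")
  if (cfg$min_overlap < 1) pg_stop("min_overlap must be >= 1")
  if (cfg$profile_flank %% cfg$bin_size != 0)
    pg_stop("profile_flank must be a multiple of bin_size")
  invisible(cfg)
}

#' Write / read a run configuration as YAML
#'
#' The YAML round-trip is lossless: `read_run_config(write_run_config(x))`
#' reproduces `x`.
#'
#' @param cfg A `RunConfig`.
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) pg_stop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    pg_stop("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full two-condition peak/expression integration pipeline
#'
#' Executes, in order: annotation and peak loading, peak partition into
#' common and condition-specific sets, feature annotation of the pooled
#' condition-specific peaks, TSS/TES signal profiling (when coverage tracks
#' are configured), gained/lost region-change classification, fold-change
#' DEG calling, the distance-bounded peak-gene association, the
#' change-by-expression intersections, and term enrichment of the
#' lost-and-down gene set (when a term map is configured). All stage outputs
#' and a manifest recording inputs, parameters, package version and seed are
#' written under `outdir`; reruns on identical inputs produce identical
#' files.
#'
#' @param config A `RunConfig` from [run_config()] (or a path to its YAML).
#' @return Invisibly, a list with all intermediate and final objects:
#'   `genes`, `partition`, `annotated`, `feature_dist`, `profiles`,
#'   `changes`, `degs`, `diff_peak_genes`, `integration`, `enrichment`,
#'   `manifest`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "RunConfig")) pg_stop("config must be a RunConfig")
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  genes <- run_stage("annotation",
                     read_annotation(cfg$annotation,
                                     chrom_sizes = cfg$chrom_sizes))
  peaks_a <- run_stage("peaks", read_peaks(cfg$peaks_treatment, "treatment"))
  peaks_b <- run_stage("peaks", read_peaks(cfg$peaks_control, "control"))

  partition <- run_stage("partition",
                         partition_peaks(peaks_a, peaks_b, cfg$min_overlap))
  specific_pool <- c(partition$specific_a, partition$specific_b)

  annotated <- run_stage("annotate", {
    if (length(specific_pool) == 0) NULL
    else annotate_peaks(specific_pool, genes,
                        promoter_up = cfg$promoter_up,
                        promoter_down = cfg$promoter_down,
                        downstream_window = cfg$downstream_window)
  })
  feature_dist <- if (is.null(annotated)) NULL else
    feature_distribution(annotated)

  profiles <- NULL
  if (!is.null(cfg$track_treatment) && !is.null(cfg$track_control)) {
    profiles <- run_stage("profile", {
      if (is.null(cfg$chrom_sizes))
        pg_stop("coverage profiling needs chrom_sizes")
      sizes <- read_chrom_sizes(cfg$chrom_sizes)
      tr_a <- read_bedgraph(cfg$track_treatment, sizes, cfg$bin_size,
                            "treatment")
      tr_b <- read_bedgraph(cfg$track_control, sizes, cfg$bin_size,
                            "control")
      list(tss_treatment = anchored_profile(tr_a, genes, "TSS",
                                            cfg$profile_flank),
           tss_control = anchored_profile(tr_b, genes, "TSS",
                                          cfg$profile_flank),
           tes_treatment = anchored_profile(tr_a, genes, "TES",
                                            cfg$profile_flank),
           tes_control = anchored_profile(tr_b, genes, "TES",
                                          cfg$profile_flank))
    })
  }

  changes <- run_stage("classify",
                       classify_region_changes(partition, genes,
                                               tss_up = cfg$promoter_up,
                                               tss_down = cfg$promoter_down,
                                               tss_exclusion =
                                                 cfg$tss_exclusion))

  integration <- NULL
  degs <- NULL
  diff_peak_genes <- character(0)
  if (!is.null(cfg$expression)) {
    degs <- run_stage("integration", {
      call_degs(read_expression(cfg$expression), cfg$fold_threshold)
    })
    diff_peak_genes <- run_stage("integration",
                                 genes_near_peaks(specific_pool, genes,
                                                  cfg$max_distance))
    integration <- run_stage("integration",
                             integrate_changes(changes, degs,
                                               diff_peak_genes))
  }

  enrichment <- NULL
  if (!is.null(cfg$terms) && !is.null(integration)) {
    enrichment <- run_stage("enrichment", {
      terms <- read_term_map(cfg$terms)
      if (length(integration$both_down) == 0) NULL
      else enrich(integration$both_down, genes$gene_id, terms, cfg$alpha)
    })
  }

  manifest <- list(
    inputs = Filter(Negate(is.null),
                    cfg[c("annotation", "peaks_treatment", "peaks_control",
                          "track_treatment", "track_control", "expression",
                          "terms", "chrom_sizes")]),
    parameters = cfg[c("promoter_up", "promoter_down", "downstream_window",
                       "max_distance", "fold_threshold", "alpha", "bin_size",
                       "tss_exclusion", "profile_flank", "min_overlap")],
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("peakgain")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  run_stage("write", {
    out <- function(f) file.path(cfg$outdir, f)
    counts <- data.frame(
      set = c("peaks_treatment", "peaks_control", "common_treatment",
              "common_control", "specific_treatment", "specific_control"),
      n = c(length(peaks_a), length(peaks_b), length(partition$common_a),
            length(partition$common_b), length(partition$specific_a),
            length(partition$specific_b)))
    write_tsv(counts, out("partition_counts.tsv"))
    if (!is.null(annotated)) {
      write_tsv(annotated, out("annotated_peaks.tsv"))
      write_tsv(feature_dist, out("feature_distribution.tsv"))
    }
    if (!is.null(profiles)) {
      write_profile_matrix(profiles$tss_treatment,
                           out("profile_tss_treatment.tsv"),
                           out("profile_tss_treatment_mean.tsv"))
      write_profile_matrix(profiles$tss_control,
                           out("profile_tss_control.tsv"),
                           out("profile_tss_control_mean.tsv"))
      write_profile_matrix(profiles$tes_treatment,
                           out("profile_tes_treatment.tsv"))
      write_profile_matrix(profiles$tes_control,
                           out("profile_tes_control.tsv"))
    }
    write_region_changes(changes, out("region_changes.tsv"))
    if (!is.null(degs))
      write_tsv(data.frame(gene_id = c(degs$up, degs$down),
                           direction = c(rep("up", length(degs$up)),
                                         rep("down", length(degs$down)))),
                out("degs.tsv"))
    if (!is.null(integration))
      write_integration(integration, out("integration.json"))
    if (!is.null(enrichment))
      write_tsv(enrichment, out("enrichment.tsv"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  })

  invisible(list(genes = genes, partition = partition, annotated = annotated,
                 feature_dist = feature_dist, profiles = profiles,
                 changes = changes, degs = degs,
                 diff_peak_genes = diff_peak_genes,
                 integration = integration, enrichment = enrichment,
                 manifest = manifest))
}

#' Run the pipeline directly on a synthetic bundle
#'
#' Convenience wrapper building a [run_config()] from a bundle's files.
#'
#' @param bundle A `SyntheticBundle` from [generate_dataset()].
#' @param outdir Output directory (default: `results/` inside the bundle).
#' @param ... Overrides passed to [run_config()].
#' @return The [run_all()] result list.
#' @export
run_on_bundle <- function(bundle, outdir = file.path(bundle$dir, "results"),
                          ...) {
  args <- list(annotation = bundle$files$annotation,
               peaks_treatment = bundle$files$peaks_treatment,
               peaks_control = bundle$files$peaks_control,
               expression = bundle$files$expression,
               chrom_sizes = bundle$files$chrom_sizes,
               track_treatment = bundle$files$track_treatment,
               track_control = bundle$files$track_control,
               terms = bundle$files$terms, outdir = outdir,
               seed = bundle$design$seed)
  over <- list(...)
  args[names(over)] <- over
  run_all(do.call(run_config, args))
}
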