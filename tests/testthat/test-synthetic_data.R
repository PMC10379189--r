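# A compact design variant keeps the unit tests fast; the default design is
# exercised in the acceptance tests.
small_design <- function(seed = 11, ...) {
  synthetic_design(n_genes = 20, n_lost_tss = 2, n_gained_tss = 1,
                   n_lost_body = 1, n_gained_body = 1, n_down = 4, n_up = 3,
                   background_peaks_per_condition = 10, seed = seed, ...)
}

test_that("design validation rejects infeasible requests", {
  expect_error(synthetic_design(n_genes = 5, n_lost_tss = 6),
               "exceed n_genes")
  expect_error(synthetic_design(n_down = 40, n_up = 20), "exceed n_genes")
  expect_error(synthetic_design(n_lost_tss = 10, n_down = 2),
               "matched DEGs")
  expect_error(synthetic_design(fold_up = 1.1), "cross fold_threshold")
  expect_error(generate_dataset(synthetic_design(n_genes = 60,
                                                 chrom_length = 1e6),
                                tempfile()), "infeasible packing")
})

test_that("a null design yields no specific peaks and no DEGs", {
  d <- synthetic_design(n_lost_tss = 0, n_gained_tss = 0, n_lost_body = 0,
                        n_gained_body = 0, n_up = 0, n_down = 0, seed = 3)
  b <- generate_dataset(d, tempfile("null"))
  part <- partition_peaks(read_peaks(b$files$peaks_treatment, "t"),
                          read_peaks(b$files$peaks_control, "c"))
  expect_equal(length(part$specific_a), 0)
  expect_equal(length(part$specific_b), 0)
  degs <- call_degs(read_expression(b$files$expression))
  expect_length(degs$up, 0)
  expect_length(degs$down, 0)
})

test_that("generation is deterministic for a fixed seed", {
  b1 <- generate_dataset(small_design(seed = 99), tempfile("det1"))
  b2 <- generate_dataset(small_design(seed = 99), tempfile("det2"))
  for (f in setdiff(names(b1$files), "annotation")) {
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]),
                     label = f)
  }
  # the GTF carries a writer date comment; the records must be identical
  strip <- function(p) grep("^#", readLines(p), value = TRUE, invert = TRUE)
  expect_identical(strip(b1$files$annotation), strip(b2$files$annotation))
  b3 <- generate_dataset(small_design(seed = 100), tempfile("det3"))
  expect_false(identical(readLines(b1$files$expression),
                         readLines(b3$files$expression)))
})

test_that("planted labels are recovered exactly by the pipeline (closure)", {
  b <- generate_dataset(small_design(seed = 17), tempfile("clos"))
  res <- run_on_bundle(b)
  got_calls <- paste(res$changes$gene_id, res$changes$region,
                     res$changes$direction)
  want_calls <- c(
    lab(b$truth$labels$gained_tss, "TSS gained"),
    lab(b$truth$labels$lost_tss, "TSS lost"),
    lab(b$truth$labels$gained_body, "gene_body gained"),
    lab(b$truth$labels$lost_body, "gene_body lost"))
  expect_setequal(got_calls, want_calls)
  expect_equal(res$degs$up, b$truth$deg$up)
  expect_equal(res$degs$down, b$truth$deg$down)
  expect_equal(res$diff_peak_genes, b$truth$diff_peak_genes)
  expect_equal(res$integration$common_genes, b$truth$expected$common_genes)
  expect_equal(res$integration$both_down, b$truth$expected$both_down)
  expect_equal(res$integration$quadrants, b$truth$expected$quadrants)
  # the planted roles equal the truth labels by construction
  expect_setequal(b$truth$labels$lost_tss, b$roles$lost_tss)
  expect_setequal(b$truth$labels$gained_tss, b$roles$gained_tss)
})

test_that("coverage tracks are consistent with the peak plateaus", {
  b <- generate_dataset(small_design(seed = 23), tempfile("cov"))
  sizes <- read_chrom_sizes(b$files$chrom_sizes)
  track <- read_bedgraph(b$files$track_control, sizes, bin_size = 50)
  pk <- read_peaks(b$files$peaks_control, "control")
  lost <- pk[grepl("^lost_", pk$name)][1]
  # a bin-aligned window inside the plateau sees the full elevated value
  centre <- (start(lost) + end(lost)) %/% 2
  aligned <- 50 * ((centre - 1) %/% 50) + 1
  inside <- GRanges(seqnames(lost), IRanges(aligned, aligned + 49))
  expect_equal(region_mean_signal(track, inside),
               b$design$baseline_coverage + b$design$peak_height)
  off_peak <- GenomicRanges::shift(lost, 5000)
  expect_equal(region_mean_signal(track, off_peak),
               b$design$baseline_coverage)
})

test_that("dropping the only evidence peak removes exactly that call", {
  b <- generate_dataset(small_design(seed = 31), tempfile("drop"))
  gene <- b$roles$lost_tss[1]
  before <- run_on_bundle(b, outdir = file.path(b$dir, "before"))
  b2 <- perturb_dataset(b, "drop_peak", sprintf("lost_TSS_%s", gene))
  after <- run_on_bundle(b2, outdir = file.path(b$dir, "after"))
  lost_before <- before$changes[before$changes$direction == "lost" &
                                  before$changes$region == "TSS", "gene_id"]
  lost_after <- after$changes[after$changes$direction == "lost" &
                                after$changes$region == "TSS", "gene_id"]
  expect_setequal(setdiff(lost_before, lost_after), gene)
  # no other call changed
  key <- function(r) paste(r$changes$gene_id, r$changes$region,
                           r$changes$direction)
  expect_setequal(setdiff(key(before), key(after)),
                  paste(gene, "TSS lost"))
  expect_length(setdiff(key(after), key(before)), 0)
  expect_false(gene %in% after$integration$quadrants$TSS_lost_down)
  expect_equal(after$integration$quadrants$TSS_lost_down,
               b2$truth$expected$quadrants$TSS_lost_down)
})

test_that("shifting a specific peak beyond the bound breaks association", {
  b <- generate_dataset(small_design(seed = 37), tempfile("shift"))
  gene <- b$roles$lost_tss[1]
  before <- run_on_bundle(b, outdir = file.path(b$dir, "before"))
  expect_true(gene %in% before$diff_peak_genes)
  # shift away from the gene (upstream of the TSS in genomic terms)
  away <- if (b$genes$strand[b$genes$gene_id == gene] == "+") -30000 else 30000
  b2 <- perturb_dataset(b, "shift_peak", sprintf("lost_TSS_%s", gene),
                        shift = away)
  after <- run_on_bundle(b2, outdir = file.path(b$dir, "after"))
  expect_false(gene %in% after$diff_peak_genes)
  expect_equal(after$diff_peak_genes, b2$truth$diff_peak_genes)
  expect_error(perturb_dataset(b, "drop_peak", "no_such_peak"),
               "unknown peak")
})

test_that("flipping a planted down gene moves it to the up set", {
  b <- generate_dataset(small_design(seed = 41), tempfile("flip"))
  gene <- b$roles$down[1]
  b2 <- perturb_dataset(b, "flip_expression", gene)
  degs <- call_degs(read_expression(b2$files$expression))
  expect_true(gene %in% degs$up)
  expect_false(gene %in% degs$down)
  expect_equal(degs$up, b2$truth$deg$up)
})
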