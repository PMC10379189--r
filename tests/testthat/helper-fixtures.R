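# Fixture builders shared across the suite. Coordinates in comments follow
# the BED 0-based half-open convention of the input formats; GRanges objects
# are 1-based closed.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Genes from a compact spec: data.frame(chrom, start0, end0, strand, gene_id)
# given in 0-based half-open coordinates, as a GTF would encode them 1-based.
make_genes <- function(df, chrom_sizes = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0), strand = df$strand)
  gr$gene_id <- df$gene_id
  gr <- peakgain:::add_tss_tes(gr)
  if (!is.null(chrom_sizes)) gr <- peakgain:::set_chrom_sizes(gr, chrom_sizes)
  peakgain:::sort_genes(gr)
}

# A planted-label vector that stays empty when the gene set is empty.
lab <- function(genes, tag) {
  if (length(genes) == 0) character(0) else paste(genes, tag)
}

# Peaks from 0-based half-open coordinates.
make_peaks <- function(chrom, start0, end0, names = NULL, label = "",
                       summit_offset = NULL) {
  gr <- if (length(start0) == 0) GRanges() else
    GRanges(chrom, IRanges(start0 + 1, end0))
  gr$name <- if (is.null(names)) sprintf("%s_p%d", label, seq_along(gr))
             else names
  gr$score <- rep(NA_real_, length(gr))
  gr$summit_offset <- if (is.null(summit_offset))
    rep(NA_integer_, length(gr)) else as.integer(summit_offset)
  gr <- peakgain:::sort_peaks(gr)
  S4Vectors::metadata(gr)$condition_label <- label
  gr
}

# Random peak set on a small genome (used by the partition property tests).
random_peakset <- function(n, label, max_coord = 5000, n_chroms = 2) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chroms)), n, replace = TRUE)
  start0 <- sample.int(max_coord, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  df <- unique(data.frame(chrom, start0, end0 = start0 + width))
  make_peaks(df$chrom, df$start0, df$end0, label = label)
}

# Write a small GTF from the same compact spec used by make_genes.
write_toy_gtf <- function(df, path) {
  lines <- sprintf('%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   df$chrom, df$start0 + 1, df$end0, df$strand, df$gene_id)
  writeLines(lines, path)
  path
}

# Write bedGraph records given 0-based half-open intervals.
write_toy_bedgraph <- function(chrom, start0, end0, value, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, start0, end0, value), path)
  path
}
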