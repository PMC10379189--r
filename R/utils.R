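#' @importFrom methods is
#' @importFrom utils read.table write.table
NULL

# Abort with a consistent message prefix; used by validators across modules.
pg_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# TSV writer with the conventions used throughout (no quotes, no rownames).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a chromosome sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the two-column TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) pg_stop("chrom sizes file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) pg_stop("chrom sizes file must have 2 columns: %s", path)
  sizes <- as.integer(df[[2]])
  if (anyNA(sizes) || any(sizes <= 0))
    pg_stop("chromosome lengths must be positive integers")
  names(sizes) <- as.character(df[[1]])
  if (anyDuplicated(names(sizes)))
    pg_stop("duplicate chromosome name in %s", path)
  sizes
}

write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(chrom = names(sizes), length = unname(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
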