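#' Upper-tail hypergeometric probability
#'
#' Exact probability of drawing at least `k` annotated genes when `n` genes
#' are drawn without replacement from a universe of `N` genes of which `K`
#' are annotated: `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @param n Query size.
#' @param K Term size.
#' @param N Background (universe) size.
#' @return The exact upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(n > N) || any(K > N) ||
      any(k > pmin(n, K)))
    pg_stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K), n, K <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotone enforcement; output order matches input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    pg_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read a term-to-gene map (GMT or two-column TSV)
#'
#' GMT files follow the usual layout (term, description, genes...); the
#' two-column TSV alternative has one `term_id<TAB>gene_id` pair per line,
#' no header.
#'
#' @param path Path to a `.gmt` file or a two-column TSV.
#' @return Named list: term id -> character vector of gene ids.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) pg_stop("term map not found: %s", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    terms <- fgsea::gmtPathways(path)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) pg_stop("term map TSV needs 2 columns")
    terms <- split(as.character(df[[2]]), as.character(df[[1]]))
  }
  terms <- lapply(terms, function(g) sort(unique(g)))
  empty <- vapply(terms, length, 0L) == 0
  if (any(empty))
    pg_stop("empty term(s): %s", paste(names(terms)[empty], collapse = ", "))
  terms
}

#' Write a term map as GMT
#'
#' @param terms Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_term_map <- function(terms, path) {
  lines <- vapply(names(terms), function(id)
    paste(c(id, id, terms[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene set against a term map
#'
#' One-sided hypergeometric test per term with at least one query hit,
#' Benjamini-Hochberg correction across the tested terms, significance at
#' `q < alpha`. Term gene sets are intersected with the background before
#' testing so genes outside the declared universe never inflate term sizes.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param terms Named list from [read_term_map()].
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @return `data.frame` sorted by (q, p, term_id) with columns `term_id`,
#'   `k`, `n`, `K`, `N`, `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query, background, terms, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) pg_stop("empty query set")
  stray <- setdiff(query, background)
  if (length(stray))
    pg_stop("query gene(s) not in background: %s",
            paste(stray, collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(terms), function(id) {
    term_genes <- intersect(terms[[id]], background)
    k <- length(intersect(query, term_genes))
    if (k == 0) return(NULL)
    K <- length(term_genes)
    data.frame(term_id = id, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
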