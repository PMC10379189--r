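# Independent brute-force oracles. These work on plain vectors extracted
# from the objects under test and never call the code paths they check.

# Per-base set-intersection overlap length of two 0-based half-open
# intervals on the same chromosome.
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1), seq.int(s2, e2 - 1)))
}

# Quadratic all-pairs >= min_overlap partition oracle on two peak GRanges;
# returns logical "is common" flags per input peak.
oracle_common_flags <- function(a, b, min_overlap = 1) {
  ac <- as.character(seqnames(a)); as0 <- start(a) - 1L; ae0 <- end(a)
  bc <- as.character(seqnames(b)); bs0 <- start(b) - 1L; be0 <- end(b)
  flag <- function(xc, xs, xe, yc, ys, ye) {
    vapply(seq_along(xc), function(i) {
      any(vapply(seq_along(yc), function(j) {
        yc[j] == xc[i] &&
          min(xe[i], ye[j]) - max(xs[i], ys[j]) >= min_overlap
      }, TRUE))
    }, TRUE)
  }
  list(a = flag(ac, as0, ae0, bc, bs0, be0),
       b = flag(bc, bs0, be0, ac, as0, ae0))
}

# All-pairs edge-to-edge gap oracle: gene ids within max_distance of any
# peak (0 gap for overlap), from raw coordinate vectors.
oracle_genes_near <- function(genes, peaks, max_distance) {
  gc <- as.character(seqnames(genes)); gs0 <- start(genes) - 1L
  ge0 <- end(genes)
  pc <- as.character(seqnames(peaks)); ps0 <- start(peaks) - 1L
  pe0 <- end(peaks)
  keep <- vapply(seq_along(gc), function(i) {
    any(vapply(seq_along(pc), function(j) {
      if (pc[j] != gc[i]) return(FALSE)
      gap <- max(0, max(ps0[j] - ge0[i], gs0[i] - pe0[j]))
      gap <= max_distance
    }, TRUE))
  }, TRUE)
  sort(genes$gene_id[keep])
}

# Exact hypergeometric upper tail by closed-form enumeration over the
# support, using only choose().
oracle_hyper_upper <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Hand-stepped BH adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# Per-base mean coverage over a 0-based half-open region, straight from
# bedGraph-style records (start0, end0, value).
oracle_region_mean <- function(records, s0, e0) {
  vals <- numeric(e0 - s0)
  for (r in seq_len(nrow(records))) {
    pos <- seq.int(records$start0[r], records$end0[r] - 1)
    hit <- pos >= s0 & pos < e0
    vals[pos[hit] - s0 + 1] <- records$value[r]
  }
  mean(vals)
}
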