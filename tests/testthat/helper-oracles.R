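# Independent oracles, deliberately naive. The enrichment-score oracle
# recomputes the running sum's prefix from scratch at every position
# (O(N^2)) instead of streaming, so it shares no code path with the
# implementation under test.

oracle_es <- function(genes, metrics, query, p = 1) {
  n <- length(genes)
  is_hit <- genes %in% query
  n_hits <- sum(is_hit)
  w <- if (p == 0) rep(1, n) else abs(metrics)^p
  n_r <- sum(w[is_hit])
  if (n_r == 0) { w <- rep(1, n); n_r <- n_hits }
  s_all <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(i)) {          # full prefix recomputation
      s <- s + if (is_hit[j]) w[j] / n_r else -1 / (n - n_hits)
    }
    s_all[i] <- s
  }
  # earliest position within tolerance of the maximal |deviation|
  s_all[which(abs(s_all) >= max(abs(s_all)) - 1e-9)[1]]
}

# ranked list with antisymmetric metric values (top and bottom magnitudes
# mirror exactly), so the enrichment-score null is symmetric about zero
symmetric_ranked <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ranked_genes(sprintf("g%05d", sample(n)), seq(1, -1, length.out = n))
}

# brute-force signal-to-noise with the GSEA variance floor, per gene
oracle_s2n <- function(xa, xb) {
  fl <- function(s, m) max(s, if (m == 0) 0.2 else 0.2 * abs(m))
  ma <- mean(xa); mb <- mean(xb)
  (ma - mb) / (fl(sd(xa), ma) + fl(sd(xb), mb))
}

# random strictly-decreasing ranked list
random_ranked <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sort(rnorm(n), decreasing = TRUE)
  m <- m + seq(n * 1e-9, 1e-9, length.out = n)   # break exact ties
  ranked_genes(sprintf("g%05d", sample(n)), m)
}

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
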