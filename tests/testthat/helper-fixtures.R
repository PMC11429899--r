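# Shared fixtures, built in code.

# Small dense count matrix wrapped as v1_counts.
toy_counts <- function(mat, sample = rep("S1", ncol(mat)),
                       genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- paste0("c", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, barcodes)
  v1_counts(Matrix::Matrix(mat, sparse = TRUE), data.frame(sample = sample))
}

# Reduced-size simulation shared across tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_counts(sim_config(n_nuclei = 4000, n_genes = 1200,
                                           seed = 7))
    cache
  }
})

# Exact two-sided rank-sum p-value by enumeration over all assignments of
# the pooled values to group A (independent oracle for the Wilcoxon path).
enumerate_ranksum_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  na <- length(xa)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  mu <- length(xa) * length(xb) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exhaustive evaluation of both component-count criteria (oracle for
# find_pc): criterion A scans every index for the first satisfying both
# conditions; criterion B scans every adjacent pair for the last large drop.
oracle_find_pc <- function(pv) {
  a <- NA_integer_
  for (k in seq_along(pv))
    if (sum(pv[seq_len(k)]) > 90 && pv[k] < 5) { a <- k; break }
  if (is.na(a)) a <- length(pv)
  b <- 1L
  if (length(pv) > 1)
    for (i in seq_len(length(pv) - 1))
      if (pv[i] - pv[i + 1] > 0.1) b <- i + 1L
  min(a, b)
}
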