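#' Build a cluster x sample composition table
#'
#' @param clusters cluster label per nucleus.
#' @param sample sample label per nucleus.
#' @param sample_meta data.frame with one row per sample: `sample`,
#'   `genotype`, `replicate` (extra columns kept).
#' @return list of class `composition_table`: `counts` (clusters x samples
#'   integer matrix), `sample_meta`.
#' @export
composition_table <- function(clusters, sample, sample_meta) {
  tab <- table(cluster = as.character(clusters),
               sample = as.character(sample))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  sample_meta <- as.data.frame(sample_meta)
  stopifnot(all(colnames(counts) %in% sample_meta$sample))
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ]
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "composition_table")
}

#' Local inverse Simpson's index over an embedding
#'
#' For every nucleus, Gaussian-kernel weights over its ~3 x perplexity
#' nearest neighbours are tuned to the target perplexity (entropy matching,
#' as in the original LISI), group probabilities are the weighted label
#' proportions, and the score is 1 / sum(p_g^2). Scores are hard-bounded in
#' [1, number of groups]: 1 means the neighbourhood holds a single group,
#' the group count means perfect intermixing.
#'
#' @param embedding nuclei x 2 (or more) coordinate matrix.
#' @param labels group label per nucleus (>= 2 groups).
#' @param perplexity effective neighbourhood size (default 30); shrunk with
#'   a warning when fewer neighbours exist.
#' @return numeric score per nucleus.
#' @export
compute_ilisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  groups <- sort(unique(labels))
  if (length(groups) < 2) return(rep(1, n))   # one group: no mixing to score
  if (n - 1 < perplexity) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning("fewer neighbours than perplexity; shrunk to ", perplexity)
  }
  k <- min(3 * perplexity, n - 1)
  nn <- RANN::nn2(embedding, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  d2 <- nn$nn.dists[, -1, drop = FALSE]^2
  target <- log(perplexity)
  scores <- numeric(n)
  gmat <- matrix(match(labels[idx], groups), nrow = n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-beta * di)
      sw <- sum(w)
      if (sw < .Machine$double.eps) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    if (sum(w) < .Machine$double.eps) { scores[i] <- 1; next }
    p <- w / sum(w)
    pg <- vapply(seq_along(groups), function(g)
      sum(p[gmat[i, ] == g]), numeric(1))
    scores[i] <- 1 / sum(pg^2)
  }
  pmin(pmax(scores, 1), length(groups))
}

#' Normalized genotype ratio per cluster
#'
#' ratio = (cluster count in genotype A / total of A) /
#'         (cluster count in genotype B / total of B), computed within each
#' replicate pair; 1 means equal representation of both genotypes. A zero
#' denominator yields `Inf` and is flagged.
#'
#' @param comp a [composition_table()] whose samples carry exactly two
#'   genotypes and matching replicate labels.
#' @param genotypes character of length 2: numerator, denominator (default
#'   the sorted genotype levels, e.g. Het over KO).
#' @return list: `ratios` (clusters x replicates), `infinite` (logical
#'   matrix flagging zero-denominator cells).
#' @export
normalized_genotype_ratio <- function(comp, genotypes = NULL) {
  stopifnot(inherits(comp, "composition_table"))
  sm <- comp$sample_meta
  if (is.null(genotypes)) genotypes <- sort(unique(sm$genotype))
  stopifnot(length(genotypes) == 2)
  reps <- sort(unique(sm$replicate))
  ratios <- matrix(NA_real_, nrow(comp$counts), length(reps),
                   dimnames = list(rownames(comp$counts), reps))
  for (r in reps) {
    a <- sm$sample[sm$replicate == r & sm$genotype == genotypes[1]]
    b <- sm$sample[sm$replicate == r & sm$genotype == genotypes[2]]
    if (length(a) != 1 || length(b) != 1)
      stop("replicate ", r, " must pair one sample per genotype")
    pa <- comp$counts[, a] / sum(comp$counts[, a])
    pb <- comp$counts[, b] / sum(comp$counts[, b])
    ratios[, r] <- pa / pb
  }
  list(ratios = ratios, infinite = !is.finite(ratios))
}

# Dirichlet-multinomial log-likelihood for one sample (counts y, alpha).
dm_loglik_one <- function(y, alpha) {
  A <- sum(alpha)
  lgamma(A) - lgamma(sum(y) + A) + sum(lgamma(y + alpha) - lgamma(alpha))
}

# Total DM log-likelihood over samples. Y: S x K; log_alpha: S x K.
dm_loglik <- function(Y, log_alpha) {
  s <- 0
  for (i in seq_len(nrow(Y)))
    s <- s + dm_loglik_one(Y[i, ], exp(log_alpha[i, ]))
  s
}

#' Bayesian Dirichlet-multinomial compositional test
#'
#' Hierarchical model for genotype effects on cluster composition: sample
#' counts are Dirichlet-multinomial with log alpha = cluster intercept +
#' genotype effect x spike-and-slab inclusion indicator; the reference
#' cluster's effect is fixed at 0 and can never be credible. Posterior
#' sampling is Metropolis-within-Gibbs with exact discrete indicators; the
#' inclusion probability of a cluster is the posterior mean of its
#' indicator. The credible set is the largest set of clusters (ordered by
#' inclusion) whose mean (1 - inclusion) is at most `fdr`. Effects are
#' reported on the log2 scale.
#'
#' @param comp a [composition_table()] with two genotypes.
#' @param reference_cluster reference cluster id (see [choose_reference()]).
#' @param fdr expected false discovery rate for the credible set
#'   (default 0.05).
#' @param chains,iter,warmup MCMC settings (defaults 4 chains x 2000
#'   iterations, half warmup).
#' @param prior_inclusion prior inclusion probability of the slab
#'   (default 0.1).
#' @param slab_sd prior sd of the genotype effect (natural-log scale).
#' @param seed integer seed.
#' @param check_convergence error when split-R-hat of any intercept exceeds
#'   1.05 (default TRUE).
#' @return list of class `dm_fit`: `table` (data.frame: cluster,
#'   effect_log2, inclusion, credible), `reference`, `ci95_log2` (per
#'   cluster, from slab draws), `rhat`, `draws`.
#' @export
dm_test <- function(comp, reference_cluster, fdr = 0.05, chains = 4,
                    iter = 2000, warmup = floor(iter / 2),
                    prior_inclusion = 0.1, slab_sd = 1.5, seed = 0L,
                    check_convergence = TRUE) {
  stopifnot(inherits(comp, "composition_table"))
  Y <- t(comp$counts)                      # samples x clusters
  K <- ncol(Y); S <- nrow(Y)
  clusters <- colnames(Y)
  stopifnot(reference_cluster %in% clusters)
  ref <- match(reference_cluster, clusters)
  geno <- factor(comp$sample_meta$genotype)
  stopifnot(nlevels(geno) == 2)
  xs <- as.numeric(geno == levels(geno)[2]) # effect of 2nd level vs 1st
  prop <- colMeans(sweep(Y, 1, rowSums(Y), "/"))

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    a <- log(prop * 100) + rnorm(K, 0, 0.1)
    b <- rnorm(K, 0, slab_sd); b[ref] <- 0
    th <- rep(0L, K)
    log_alpha <- function(a, b, th)
      outer(rep(1, S), a) + outer(xs, b * th)
    ll <- dm_loglik(Y, log_alpha(a, b, th))
    n_keep <- iter - warmup
    draws_a <- matrix(NA_real_, n_keep, K)
    draws_b <- matrix(NA_real_, n_keep, K)
    draws_t <- matrix(NA_integer_, n_keep, K)
    prior_a <- function(a)
      sum(stats::dnorm(a, log(prop * 100), 5, log = TRUE))
    for (it in seq_len(iter)) {
      ## joint scale move: shift every intercept by a common delta; the
      ## overall concentration sum(alpha) mixes poorly under
      ## per-coordinate walks alone
      delta <- rnorm(1, 0, 0.3)
      ll_new <- dm_loglik(Y, log_alpha(a + delta, b, th))
      if (log(runif(1)) < ll_new - ll + prior_a(a + delta) - prior_a(a)) {
        a <- a + delta; ll <- ll_new
      }
      for (k in seq_len(K)) {
        ## intercept update
        prop_a <- a; prop_a[k] <- a[k] + rnorm(1, 0, 0.2)
        ll_new <- dm_loglik(Y, log_alpha(prop_a, b, th))
        lr <- ll_new - ll +
          stats::dnorm(prop_a[k], log(prop[k] * 100), 5, log = TRUE) -
          stats::dnorm(a[k], log(prop[k] * 100), 5, log = TRUE)
        if (log(runif(1)) < lr) { a <- prop_a; ll <- ll_new }
        if (k == ref) next
        ## slab update
        if (th[k] == 1L) {
          prop_b <- b; prop_b[k] <- b[k] + rnorm(1, 0, 0.3)
          ll_new <- dm_loglik(Y, log_alpha(a, prop_b, th))
          lr <- ll_new - ll +
            stats::dnorm(prop_b[k], 0, slab_sd, log = TRUE) -
            stats::dnorm(b[k], 0, slab_sd, log = TRUE)
          if (log(runif(1)) < lr) { b <- prop_b; ll <- ll_new }
        } else {
          b[k] <- rnorm(1, 0, slab_sd)     # prior draw; likelihood unchanged
        }
        ## indicator flip
        prop_t <- th; prop_t[k] <- 1L - th[k]
        ll_new <- dm_loglik(Y, log_alpha(a, b, prop_t))
        prior_odds <- if (prop_t[k] == 1L)
          log(prior_inclusion) - log(1 - prior_inclusion)
        else log(1 - prior_inclusion) - log(prior_inclusion)
        if (log(runif(1)) < ll_new - ll + prior_odds) {
          th <- prop_t; ll <- ll_new
        }
      }
      if (it > warmup) {
        draws_a[it - warmup, ] <- a
        draws_b[it - warmup, ] <- b
        draws_t[it - warmup, ] <- th
      }
    }
    list(a = draws_a, b = draws_b, t = draws_t)
  }

  res <- lapply(seq_len(chains), function(c) run_chain(seed + c * 1000L))
  all_b <- do.call(rbind, lapply(res, `[[`, "b"))
  all_t <- do.call(rbind, lapply(res, `[[`, "t"))

  rhat <- vapply(seq_len(K), function(k)
    split_rhat(lapply(res, function(r) r$a[, k])), numeric(1))
  if (check_convergence && any(rhat > 1.05, na.rm = TRUE))
    stop("MCMC did not converge: max split-R-hat = ",
         round(max(rhat, na.rm = TRUE), 3),
         "; increase iter or chains")

  inclusion <- colMeans(all_t)
  inclusion[ref] <- 0
  effect_log2 <- colMeans(all_b * all_t) / log(2)
  effect_log2[ref] <- 0
  ci <- t(vapply(seq_len(K), function(k) {
    sel <- all_t[, k] == 1L
    if (sum(sel) >= 20)
      stats::quantile(all_b[sel, k] / log(2), c(0.025, 0.975))
    else c(NA_real_, NA_real_)
  }, numeric(2)))
  dimnames(ci) <- list(clusters, c("lo", "hi"))

  ord <- order(inclusion, decreasing = TRUE)
  credible <- rep(FALSE, K)
  for (m in seq_len(K)) {
    if (mean(1 - inclusion[ord[seq_len(m)]]) <= fdr)
      credible[ord[seq_len(m)]] <- TRUE
    else break
  }
  credible[ref] <- FALSE
  tab <- data.frame(cluster = clusters, effect_log2 = effect_log2,
                    inclusion = inclusion, credible = credible,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, reference = reference_cluster,
                 ci95_log2 = ci, rhat = rhat,
                 draws = list(b = all_b, t = all_t)),
            class = "dm_fit")
}

# Split-R-hat across chains (each element of `chains_list` a numeric vector).
split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Choose a reference cluster for compositional testing
#'
#' Restricts to clusters whose mean relative abundance is above the median,
#' then ranks by smallest absolute change in relative abundance between
#' genotypes, breaking ties by least dispersion of relative abundance
#' across samples, then by higher abundance, then by lowest cluster id.
#'
#' @param comp a [composition_table()].
#' @return reference cluster id (character).
#' @export
choose_reference <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  rel <- sweep(comp$counts, 2, colSums(comp$counts), "/")
  abund <- rowMeans(rel)
  geno <- comp$sample_meta$genotype
  gl <- unique(geno)
  change <- if (length(gl) == 2)
    abs(rowMeans(rel[, geno == gl[1], drop = FALSE]) -
          rowMeans(rel[, geno == gl[2], drop = FALSE]))
  else rep(0, nrow(rel))
  disp <- apply(rel, 1, stats::sd)
  cand <- which(abund >= stats::median(abund))
  ord <- cand[order(change[cand], disp[cand], -abund[cand],
                    rownames(rel)[cand])]
  rownames(rel)[ord[1]]
}
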