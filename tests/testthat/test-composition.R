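ko_comp_fixture <- function(seed, deplete = TRUE, n_nuclei = 8000) {
  cfg <- sim_config(n_nuclei = n_nuclei, n_genes = 60,
                    cluster_spec = ko_cluster_spec(),
                    clade_marker_map =
                      default_clade_markers(ko_cluster_spec()),
                    samples = ko_samples(), contaminant_spec = list(),
                    doublet_rate = 0, ambient_fraction = 0,
                    depletion_spec = if (deplete)
                      list(cluster = "10", genotype = "KO",
                           log2fc = -log2(3)) else NULL,
                    seed = seed)
  tr <- simulate_counts(cfg)$truth
  composition_table(tr$cluster, tr$sample,
                    unique(tr[, c("sample", "genotype", "replicate")]))
}

test_that("iLISI respects its hard bounds and degenerate cases", {
  set.seed(2)
  emb <- matrix(rnorm(200), 100, 2)
  ## single group: no mixing to measure
  expect_equal(compute_ilisi(emb, rep("a", 100)), rep(1, 100))
  ## two fully separated groups: scores near 1, never outside [1, 2]
  emb2 <- rbind(matrix(rnorm(100), 50, 2),
                matrix(rnorm(100) + 50, 50, 2))
  s2 <- compute_ilisi(emb2, rep(c("a", "b"), each = 50), perplexity = 10)
  expect_true(all(s2 >= 1 & s2 <= 2))
  expect_lt(median(s2), 1.05)
  ## tiny data: perplexity shrunk with a warning, bounds still hold
  expect_warning(s3 <- compute_ilisi(emb[1:8, ], rep(c("a", "b"), 4),
                                     perplexity = 30), "shrunk")
  expect_true(all(s3 >= 1 & s3 <= 2))
})

test_that("iLISI approaches the group count on an interleaved lattice", {
  g <- expand.grid(x = 1:24, y = 1:24)
  labels <- paste0("age", (g$x + 2 * g$y) %% 4)
  s <- compute_ilisi(as.matrix(g), labels, perplexity = 20)
  expect_true(all(s >= 1 & s <= 4))
  expect_gt(median(s), 3.5)
})

test_that("normalized genotype ratios match hand computation and symmetry", {
  counts <- matrix(c(10, 90, 5, 95), nrow = 2,
                   dimnames = list(c("c1", "c2"), c("Het_R1", "KO_R1")))
  meta <- data.frame(sample = c("Het_R1", "KO_R1"),
                     genotype = c("Het", "KO"), replicate = "R1")
  comp <- structure(list(counts = counts, sample_meta = meta),
                    class = "composition_table")
  r <- normalized_genotype_ratio(comp, c("Het", "KO"))
  expect_equal(unname(r$ratios["c1", "R1"]), 2)       # (10/100)/(5/100)
  ## label swap inverts every ratio
  r_swap <- normalized_genotype_ratio(comp, c("KO", "Het"))
  expect_equal(r_swap$ratios, 1 / r$ratios)
  ## scale invariance in either genotype's totals
  comp2 <- comp
  comp2$counts[, "KO_R1"] <- comp$counts[, "KO_R1"] * 7
  r2 <- normalized_genotype_ratio(comp2, c("Het", "KO"))
  expect_equal(r2$ratios, r$ratios)
  ## identical compositions give 1 everywhere
  comp3 <- comp
  comp3$counts[, "KO_R1"] <- comp$counts[, "Het_R1"] * 3
  r3 <- normalized_genotype_ratio(comp3, c("Het", "KO"))
  expect_equal(unname(r3$ratios[, "R1"]), c(1, 1))
  ## zero denominator flagged as infinite
  comp4 <- comp
  comp4$counts["c1", "KO_R1"] <- 0
  r4 <- normalized_genotype_ratio(comp4, c("Het", "KO"))
  expect_true(r4$infinite["c1", "R1"])
})

test_that("reference choice matches a brute-force ranking oracle", {
  counts <- matrix(c(30, 25, 45,
                     30, 25, 45,
                     25, 30, 45,
                     25, 30, 45), nrow = 3,
                   dimnames = list(c("c1", "c2", "c3"),
                                   c("H1", "H2", "K1", "K2")))
  meta <- data.frame(sample = c("H1", "H2", "K1", "K2"),
                     genotype = c("Het", "Het", "KO", "KO"),
                     replicate = c("R1", "R2", "R1", "R2"))
  comp <- structure(list(counts = counts, sample_meta = meta),
                    class = "composition_table")
  ## oracle: restrict to above-median abundance, order by |change| then
  ## dispersion then -abundance then id
  rel <- sweep(counts, 2, colSums(counts), "/")
  abund <- rowMeans(rel)
  change <- abs(rowMeans(rel[, 1:2]) - rowMeans(rel[, 3:4]))
  disp <- apply(rel, 1, sd)
  expect_equal(choose_reference(comp), "c3")   # stable, high, unchanged
  ## all clusters identical: lowest id wins
  counts_eq <- matrix(25, 3, 4, dimnames = dimnames(counts))
  comp_eq <- structure(list(counts = counts_eq, sample_meta = meta),
                       class = "composition_table")
  expect_equal(choose_reference(comp_eq), "c1")
  ## a stable abundant cluster is preferred over a changing one
  brute <- local({
    cand2 <- rownames(counts)[abund >= median(abund)]
    ord <- cand2[order(change[cand2], disp[cand2], -abund[cand2], cand2)]
    ord[1]
  })
  expect_equal(choose_reference(comp), brute)
})

test_that("DM test recovers a planted 3-fold depletion and honors the
          reference constraint", {
  comp <- ko_comp_fixture(seed = 11)
  fit <- dm_test(comp, reference_cluster = "2", seed = 1, chains = 4,
                 iter = 1500)
  tab <- fit$table
  ref_row <- tab[tab$cluster == "2", ]
  expect_equal(ref_row$effect_log2, 0)
  expect_equal(ref_row$inclusion, 0)
  expect_false(ref_row$credible)
  ## only the depleted cluster is credible
  expect_true(tab$credible[tab$cluster == "10"])
  expect_equal(sum(tab$credible), 1)
  ## -log2(3) inside the posterior 95% interval of the effect
  ci <- fit$ci95_log2["10", ]
  expect_gte(-log2(3), ci["lo"])
  expect_lte(-log2(3), ci["hi"])
  ## direction and magnitude are sane
  expect_lt(tab$effect_log2[tab$cluster == "10"], -1)
})

test_that("DM test is seed-reproducible and quiet under the null", {
  comp <- ko_comp_fixture(seed = 11)
  f1 <- dm_test(comp, "2", seed = 7, chains = 2, iter = 800,
                check_convergence = FALSE)
  f2 <- dm_test(comp, "2", seed = 7, chains = 2, iter = 800,
                check_convergence = FALSE)
  expect_identical(f1$table, f2$table)
  ## a handful of null datasets: no credible effects
  for (s in 1:4) {
    compn <- ko_comp_fixture(seed = 200 + s, deplete = FALSE,
                             n_nuclei = 4000)
    fitn <- dm_test(compn, "2", seed = 1, chains = 2, iter = 600,
                    check_convergence = FALSE)
    expect_false(any(fitn$table$credible), label = paste("null seed", s))
  }
})
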