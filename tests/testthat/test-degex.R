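test_that("rank-sum p-values match the enumeration oracle (sizes <= 8)", {
  set.seed(101)
  ## A={1,2,3} vs B={4,5,6}: exact two-sided p = 0.1
  m <- Matrix::Matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                             dimnames = list("g1", paste0("c", 1:6))),
                      sparse = TRUE)
  de <- wilcoxon_de(m, 1:3, 4:6)
  expect_equal(de$p, 0.1)
  expect_equal(de$p, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)))

  ## randomized tie-free fixtures across group sizes
  for (r in 1:60) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    xa <- rnorm(na); xb <- rnorm(nb)
    mm <- Matrix::Matrix(matrix(c(xa, xb), nrow = 1,
                                dimnames = list("g",
                                                paste0("c",
                                                       seq_len(na + nb)))),
                         sparse = TRUE)
    got <- wilcoxon_de(mm, seq_len(na), na + seq_len(nb))$p
    expect_equal(got, enumerate_ranksum_p(xa, xb), tolerance = 1e-12,
                 label = paste("sizes", na, nb, "rep", r))
  }
})

test_that("fold changes and significance obey the strict 0.25 rule", {
  ## identical groups: log2FC 0 and p near 1
  v <- rep(c(1, 2, 3), 4)
  m <- Matrix::Matrix(matrix(v, nrow = 1,
                             dimnames = list("g", paste0("c", 1:12))),
                      sparse = TRUE)
  de <- wilcoxon_de(m, 1:6, 7:12)
  expect_equal(de$log2fc, 0)
  expect_gte(de$p, 0.9)
  expect_false(de$significant)

  ## |log2FC| exactly 0.25 is not significant (strict >)
  ## construct groups whose expm1-means give ratio 2^0.25 exactly
  target <- 2^0.25
  a_val <- log1p(target * 3 - 1)           # mean(expm1 a) + 1 = 3*2^0.25
  m2 <- Matrix::Matrix(matrix(c(rep(a_val, 20), rep(log1p(2), 20)),
                              nrow = 1,
                              dimnames = list("g", paste0("c", 1:40))),
                       sparse = TRUE)
  de2 <- wilcoxon_de(m2, 1:20, 21:40)
  expect_equal(abs(de2$log2fc), 0.25, tolerance = 1e-9)
  expect_lt(de2$p_adj, 0.05)
  ## strictness at the boundary: a cutoff equal to |log2FC| excludes the
  ## gene (> is strict), a cutoff just below admits it
  at <- wilcoxon_de(m2, 1:20, 21:40, lfc_cut = abs(de2$log2fc))
  expect_false(at$significant)
  below <- wilcoxon_de(m2, 1:20, 21:40,
                       lfc_cut = abs(de2$log2fc) - 1e-6)
  expect_true(below$significant)

  ## Bonferroni never decreases p and caps at 1
  set.seed(5)
  mm <- Matrix::Matrix(matrix(rnorm(50 * 20, 2), nrow = 50,
                              dimnames = list(paste0("g", 1:50),
                                              paste0("c", 1:20))),
                       sparse = TRUE)
  de3 <- wilcoxon_de(mm, 1:10, 11:20)
  expect_true(all(de3$p_adj >= de3$p))
  expect_true(all(de3$p_adj <= 1))
})

test_that("marker finding ranks planted genes first with mirrored signs", {
  set.seed(8)
  n_per <- 40
  cl <- rep(c("a", "b"), each = n_per)
  base <- matrix(abs(rnorm(30 * 2 * n_per, 1, 0.2)), nrow = 30)
  base[5, cl == "a"] <- base[5, cl == "a"] + 3   # planted marker of a
  rownames(base) <- paste0("g", 1:30)
  colnames(base) <- paste0("c", seq_len(2 * n_per))
  m <- Matrix::Matrix(base, sparse = TRUE)
  mk <- find_markers(m, cl)
  expect_equal(mk$a$gene[1], "g5")
  expect_false("g5" %in% mk$b$gene)
  de_ab <- wilcoxon_de(m, cl == "a", cl == "b")
  de_ba <- wilcoxon_de(m, cl == "b", cl == "a")
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-12)
  expect_error(find_markers(m, rep("a", 2 * n_per)), "two clusters")
})

test_that("age groupings recover planted P0-specific genes", {
  set.seed(31)
  ages <- rep(c("P0", "P14", "P28", "P56"), each = 50)
  genes <- paste0("g", 1:60)
  base <- matrix(abs(rnorm(60 * 200, 1, 0.3)), nrow = 60,
                 dimnames = list(genes, paste0("c", 1:200)))
  planted <- paste0("g", 1:15)
  base[planted, ages == "P0"] <- base[planted, ages == "P0"] + 2
  ## a gene increasing monotonically with age
  base["g60", ] <- base["g60", ] +
    rep(c(0, 1, 2, 3), each = 50)
  m <- Matrix::Matrix(base, sparse = TRUE)
  degs <- age_degs(m, ages)
  expect_gte(sum(planted %in% degs$P0$gene), 14)   # >= 90% recovery
  expect_true("g60" %in% degs$P28_P56$gene)
  expect_false("g60" %in% degs$P0$gene)
})

test_that("pseudobulk sums are exact, conservative and linear", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  x <- toy_counts(m)
  ## 2x3 toy aggregated to 1 group: hand-checked sums
  agg1 <- pseudobulk(x, rep("all", 3))
  expect_equal(agg1[, "all"], c(g1 = 9, g2 = 12))
  agg2 <- pseudobulk(x, c("u", "u", "v"))
  expect_equal(agg2[, "u"], c(g1 = 4, g2 = 6))
  expect_equal(agg2[, "v"], c(g1 = 5, g2 = 6))
  ## conservation and linearity
  expect_equal(sum(agg2), sum(m))
  expect_equal(rowSums(agg2), agg1[, "all"])
  ## single-nucleus group equals the nucleus
  agg3 <- pseudobulk(x, c("a", "b", "c"))
  expect_equal(unname(agg3[, "b"]), unname(m[, 2]))
  expect_error(pseudobulk(x, factor(c("a", "a", "a"),
                                    levels = c("a", "b"))), "empty")
})

test_that("pseudobulk NB-Wald recovers a planted effect and matches DESeq2
          direction on size factors", {
  set.seed(77)
  n_genes <- 300
  mu <- rlnorm(n_genes, 5, 1)
  counts <- sapply(1:6, function(i)
    rnbinom(n_genes, mu = mu * c(1, 1.1, 0.9, 1.05, 0.95, 1)[i],
            size = 10))
  rownames(counts) <- paste0("g", 1:n_genes)
  colnames(counts) <- paste0("s", 1:6)
  cond <- rep(c("ctrl", "treat"), each = 3)
  ## planted 4-fold up gene in treat
  counts["g1", cond == "treat"] <- rnbinom(3, mu = mu[1] * 4, size = 10)
  de <- pseudobulk_de(counts, cond)
  g1 <- de[de$gene == "g1", ]
  expect_lt(abs(g1$log2fc - 2), 2 * g1$se + 0.5)   # CI covers log2(4)
  expect_lt(g1$p_adj, 0.05)
  ## size factors for depth-scaled duplicates equal the scale ratio
  dup <- cbind(a = counts[, 1], b = counts[, 1] * 3)
  sf <- attr(pseudobulk_de(cbind(counts[, 1:2], dup * 1),
                           c("x", "x", "y", "y")), "size_factors")
  expect_equal(unname(sf["b"] / sf["a"]), 3, tolerance = 1e-6)
  expect_error(pseudobulk_de(counts[, c(1, 4)], c("ctrl", "treat")),
               "two samples")
})

test_that("pseudobulk NB-Wald agrees with an independent NB pipeline on a
          planted effect", {
  skip_if_not_installed("DESeq2")
  set.seed(55)
  n_genes <- 200
  mu <- rlnorm(n_genes, 5, 1)
  counts <- sapply(1:6, function(i) rnbinom(n_genes, mu = mu, size = 10))
  rownames(counts) <- paste0("g", 1:n_genes)
  colnames(counts) <- paste0("s", 1:6)
  cond <- rep(c("ctrl", "treat"), each = 3)
  counts["g1", cond == "treat"] <- rnbinom(3, mu = mu[1] * 4, size = 10)
  mine <- pseudobulk_de(counts, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(condition = factor(cond)), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ## the planted gene: same direction, similar magnitude, both significant
  expect_lt(abs(mine$log2fc[mine$gene == "g1"] - res["g1", "log2FoldChange"]),
            0.5)
  expect_lt(res["g1", "padj"], 0.05)
  expect_lt(mine$p_adj[mine$gene == "g1"], 0.05)
  ## size factors agree closely (same median-of-ratios definition)
  expect_equal(unname(attr(mine, "size_factors")),
               unname(DESeq2::sizeFactors(dds)), tolerance = 0.05)
})

test_that("null pseudobulk comparisons stay at the nominal error rate", {
  set.seed(123)
  n_genes <- 400
  mu <- rlnorm(n_genes, 4, 1)
  counts <- sapply(1:8, function(i) rnbinom(n_genes, mu = mu, size = 8))
  rownames(counts) <- paste0("g", 1:n_genes)
  colnames(counts) <- paste0("s", 1:8)
  de <- pseudobulk_de(counts, rep(c("a", "b"), each = 4))
  expect_lt(mean(de$p < 0.05, na.rm = TRUE), 0.12)
  ## FDR-adjusted discoveries stay near zero under the null (the minimal
  ## Wald test is mildly anti-conservative at small replicate counts)
  expect_lt(mean(de$p_adj < 0.05, na.rm = TRUE), 0.02)
})

test_that("cluster tree and correlation follow average-linkage oracle", {
  ## 3 clusters with known pairwise distances: merge order by hand
  prof <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  tree <- cluster_tree(prof)
  ## a and b merge first at height 1; c joins at mean(9, 10) = 9.5
  expect_equal(tree$height, c(1, 9.5))
  first <- tree$merge[1, ]
  expect_setequal(tree$labels[-first], c("a", "b"))
  ## duplicated profiles: correlation 1 and first merge at height 0
  prof2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 1, 0))
  expect_equal(cluster_correlation(prof2)["a", "b"], 1)
  tree2 <- cluster_tree(prof2)
  expect_equal(tree2$height[1], 0)
  ## correlation matrix symmetric, unit diagonal, PSD
  set.seed(2)
  prof3 <- matrix(rnorm(5 * 20), 5, dimnames = list(letters[1:5], NULL))
  cc <- cluster_correlation(prof3)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_gte(min(eigen(cc, symmetric = TRUE)$values), -1e-10)
  ## newick serialization round-trips leaf names
  tf <- tempfile(fileext = ".nwk")
  write_tree_newick(tree, tf)
  expect_setequal(ape::read.tree(tf)$tip.label, c("a", "b", "c"))
})
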