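#' Wilcoxon rank-sum differential expression between two groups
#'
#' Two-sided rank-sum test per gene. For small tie-free comparisons (both
#' groups at most `exact_max`) the exact null distribution is used;
#' otherwise the normal approximation with tie correction. The fold change
#' is log2((mean(expm1 a) + 1) / (mean(expm1 b) + 1)), the pseudocount
#' convention of log-normalized single-cell workflows. Significance
#' additionally requires |log2FC| strictly greater than `lfc_cut` after
#' Bonferroni adjustment over the genes tested.
#'
#' @param norm normalized gene x nucleus matrix.
#' @param idx_a,idx_b column indices (or logical masks) of the two groups.
#' @param genes genes to test (default all rows).
#' @param lfc_cut absolute log2 fold-change cutoff (default 0.25, strict).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param exact_max largest group size for which the exact distribution is
#'   used when there are no ties.
#' @return data.frame per gene: `gene`, `statistic` (rank-sum W of group
#'   A), `p`, `p_adj` (Bonferroni, capped at 1), `log2fc`, `direction`,
#'   `significant`.
#' @export
wilcoxon_de <- function(norm, idx_a, idx_b, genes = rownames(norm),
                        lfc_cut = 0.25, alpha = 0.05, exact_max = 10) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing))
    stop("gene(s) absent: ", paste(utils::head(missing, 5), collapse = ", "))
  a <- norm[genes, idx_a, drop = FALSE]
  b <- norm[genes, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty")
  am <- as.matrix(a); bm <- as.matrix(b)
  p <- numeric(length(genes)); W <- numeric(length(genes))
  for (g in seq_along(genes)) {
    res <- ranksum_test(am[g, ], bm[g, ], exact_max)
    W[g] <- res$W; p[g] <- res$p
  }
  lfc <- log2((rowMeans(expm1(am)) + 1) / (rowMeans(expm1(bm)) + 1))
  p_adj <- pmin(1, p * length(genes))
  data.frame(gene = genes, statistic = W, p = p, p_adj = p_adj,
             log2fc = lfc,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down",
                                                      "none")),
             significant = p_adj < alpha & abs(lfc) > lfc_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Core two-sided rank-sum test. Returns W (Mann-Whitney U of group a) and p.
ranksum_test <- function(xa, xb, exact_max = 10) {
  na <- length(xa); nb <- length(xb)
  r <- rank(c(xa, xb))
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2     # Mann-Whitney U
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && na <= exact_max && nb <= exact_max) {
    p <- 2 * min(stats::pwilcox(W, na, nb),
                 stats::pwilcox(W - 1, na, nb, lower.tail = FALSE))
    return(list(W = W, p = min(1, p)))
  }
  mu <- na * nb / 2
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2) # continuity correction
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Cluster marker genes by one-vs-rest (or pairwise) Wilcoxon tests
#'
#' For each cluster, genes passing Bonferroni-adjusted p < alpha and
#' |log2FC| > 0.25 are returned ranked by log2 fold-change, largest first.
#'
#' @param norm normalized gene x nucleus matrix.
#' @param clusters cluster label per nucleus (>= 2 clusters).
#' @param mode "one_vs_rest" (default) or "pairwise".
#' @param genes genes to test.
#' @param ... passed to [wilcoxon_de()].
#' @return named list (per cluster, or per cluster pair for pairwise) of
#'   marker data.frames.
#' @export
find_markers <- function(norm, clusters, mode = c("one_vs_rest",
                                                  "pairwise"),
                         genes = rownames(norm), ...) {
  mode <- match.arg(mode)
  cl <- as.character(clusters)
  levels <- sort(unique(cl))
  if (length(levels) < 2) stop("need at least two clusters")
  rank_up <- function(de) {
    de <- de[de$significant & de$log2fc > 0, , drop = FALSE]
    de[order(de$log2fc, decreasing = TRUE), , drop = FALSE]
  }
  if (mode == "one_vs_rest") {
    out <- lapply(levels, function(c1)
      rank_up(wilcoxon_de(norm, cl == c1, cl != c1, genes = genes, ...)))
    names(out) <- levels
  } else {
    pairs <- utils::combn(levels, 2, simplify = FALSE)
    out <- lapply(pairs, function(pr)
      rank_up(wilcoxon_de(norm, cl == pr[1], cl == pr[2], genes = genes,
                          ...)))
    names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  }
  out
}

#' Age-enriched gene sets
#'
#' One-vs-rest Wilcoxon tests for the stated age groupings (P0 versus all
#' other ages; P28 and P56 combined versus the rest), keeping genes that
#' are positively enriched (log2FC > 0) at Bonferroni-adjusted p < alpha.
#'
#' @param norm normalized gene x nucleus matrix.
#' @param age age label per nucleus.
#' @param groupings named list of character vectors of ages forming each
#'   grouping (default `list(P0 = "P0", P28_P56 = c("P28", "P56"))`).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param genes genes to test.
#' @return named list of data.frames (the enriched genes per grouping,
#'   ranked by log2FC).
#' @export
age_degs <- function(norm, age, groupings = list(P0 = "P0",
                                                 P28_P56 = c("P28", "P56")),
                     alpha = 0.05, genes = rownames(norm)) {
  age <- as.character(age)
  out <- lapply(groupings, function(gr) {
    sel <- age %in% gr
    if (!any(sel) || all(sel)) return(NULL)
    de <- wilcoxon_de(norm, sel, !sel, genes = genes, alpha = alpha,
                      lfc_cut = 0)
    de <- de[de$p_adj < alpha & de$log2fc > 0, , drop = FALSE]
    de[order(de$log2fc, decreasing = TRUE), , drop = FALSE]
  })
  out
}

#' Pseudo-bulk aggregation by raw-count summation
#'
#' Sums raw counts over all nuclei of each group; totals are conserved
#' exactly, and aggregation is linear over unions of groups.
#'
#' @param x a [v1_counts] object or raw sparse matrix.
#' @param grouping group label per nucleus; empty groups are an error.
#' @return dense gene x group integer matrix.
#' @export
pseudobulk <- function(x, grouping) {
  m <- if (inherits(x, "v1_counts")) x$counts else x
  grouping <- as.factor(grouping)         # supplied levels preserved
  if (any(table(grouping) == 0)) stop("empty group in grouping")
  stopifnot(length(grouping) == ncol(m))
  mm <- Matrix::sparseMatrix(i = seq_along(grouping),
                             j = as.integer(grouping), x = 1,
                             dims = c(length(grouping), nlevels(grouping)))
  out <- as.matrix(m %*% mm)
  dimnames(out) <- list(rownames(m), levels(grouping))
  out
}

#' Minimal negative-binomial Wald test on pseudo-bulk counts
#'
#' Count-based differential expression contract: median-of-ratios size
#' factors, per-gene method-of-moments NB dispersion (floored at 1e-8)
#' pooled within condition, a Wald z-test on the log2 fold-change of
#' normalized means, and Benjamini-Hochberg adjustment. This is a
#' deliberately minimal stand-in for a full bulk pipeline, adequate for
#' well-replicated pseudo-bulk contrasts.
#'
#' @param agg gene x sample matrix of summed raw counts.
#' @param condition factor of length ncol(agg) with two levels; at least
#'   two samples per level are required (no dispersion estimate otherwise).
#' @param pseudo_mu small mean offset guarding logs of zero means.
#' @return data.frame per gene: `gene`, `log2fc` (level 2 vs level 1),
#'   `se`, `z`, `p`, `p_adj`, plus `attr(, "size_factors")`.
#' @export
pseudobulk_de <- function(agg, condition, pseudo_mu = 1e-8) {
  condition <- factor(condition)
  stopifnot(nlevels(condition) == 2, ncol(agg) == length(condition))
  if (any(table(condition) < 2))
    stop("need at least two samples per condition for dispersion")
  sf <- median_ratio_size_factors(agg)
  norm <- sweep(agg, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  ## pooled method-of-moments dispersion on normalized counts
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  n1 <- sum(g1); n2 <- sum(g2)
  disp <- ((n1 - 1) * (v1 - mu1) / pmax(mu1, pseudo_mu)^2 +
             (n2 - 1) * (v2 - mu2) / pmax(mu2, pseudo_mu)^2) /
    (n1 + n2 - 2)
  disp <- pmax(disp, 1e-8)
  lfc <- log2((mu2 + pseudo_mu) / (mu1 + pseudo_mu))
  ## delta-method SE of log fold change under NB variance mu + disp*mu^2
  se_ln <- sqrt((1 / pmax(mu1, pseudo_mu) + disp) / n1 +
                  (1 / pmax(mu2, pseudo_mu) + disp) / n2)
  se <- se_ln / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene = rownames(agg), log2fc = lfc, se = se, z = z,
                    p = p, p_adj = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "size_factors") <- sf
  out
}

# Median-of-ratios size factors (geometric-mean reference over genes
# positive in every sample).
median_ratio_size_factors <- function(agg) {
  lg <- log(agg)
  ok <- is.finite(rowSums(lg))
  if (!any(ok)) stop("no gene is positive in every sample")
  ref <- rowMeans(lg[ok, , drop = FALSE])
  sf <- apply(lg[ok, , drop = FALSE], 2, function(col)
    exp(stats::median(col - ref)))
  sf / exp(mean(log(sf)))
}

#' Agglomerative cluster tree and correlation structure
#'
#' `cluster_tree` builds an average-linkage dendrogram on Euclidean
#' distances between per-cluster mean profiles (typically in PC space);
#' `cluster_correlation` computes the Pearson correlation matrix of
#' per-cluster mean log-normalized expression over all genes.
#'
#' @param profiles clusters x features matrix of per-cluster means (PC
#'   scores for the tree; all-gene normalized means for correlation).
#' @return `cluster_tree`: an `hclust` object (leaves = cluster ids);
#'   `cluster_correlation`: symmetric correlation matrix with unit
#'   diagonal.
#' @export
cluster_tree <- function(profiles) {
  stopifnot(nrow(profiles) >= 2)
  stats::hclust(stats::dist(profiles), method = "average")
}

#' @rdname cluster_tree
#' @export
cluster_correlation <- function(profiles) {
  stopifnot(nrow(profiles) >= 2)
  stats::cor(t(profiles))
}

#' Per-cluster mean profiles
#'
#' @param mat features x nucleus matrix (normalized values or PC scores
#'   transposed appropriately).
#' @param clusters cluster label per nucleus.
#' @return clusters x features matrix of means.
#' @export
cluster_means <- function(mat, clusters) {
  cl <- factor(as.character(clusters))
  mm <- Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(cl),
                             x = 1 / as.vector(table(cl))[as.integer(cl)],
                             dims = c(length(cl), nlevels(cl)))
  out <- as.matrix(mat %*% mm)
  colnames(out) <- levels(cl)
  t(out)
}

#' Serialize a cluster tree as Newick
#'
#' @param tree an `hclust` from [cluster_tree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
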