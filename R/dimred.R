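#' Log-normalize raw counts per 10,000
#'
#' value = ln(1 + 10000 * count / nucleus_total), natural log by default.
#' Zero counts map to exactly 0, so sparsity is preserved; the transform is
#' invariant to rescaling a nucleus's counts together with its total.
#'
#' @param x a [v1_counts] object or a sparse gene x nucleus matrix.
#' @param scale_factor library-size target (default 1e4).
#' @param base log base (default `exp(1)`).
#' @return sparse gene x nucleus matrix of normalized values.
#' @export
lognormalize <- function(x, scale_factor = 1e4, base = exp(1)) {
  m <- if (inherits(x, "v1_counts")) x$counts else
    methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("zero-total nucleus encountered; run QC first")
  m <- m %*% Matrix::Diagonal(x = scale_factor / totals)
  m@x <- log1p(m@x) / log(base)
  dimnames(m) <- if (inherits(x, "v1_counts")) dimnames(x$counts) else
    dimnames(x)
  m
}

#' Rank genes by variance-stabilized standardized variance
#'
#' Fits a loess trend of log10(variance) on log10(mean) over the raw counts,
#' standardizes each gene by its expected standard deviation (values clipped
#' at sqrt(n)), and ranks genes by the variance of the standardized values
#' ("vst" ranking). Constant genes are never selected.
#'
#' @param counts sparse gene x nucleus raw count matrix (or [v1_counts]).
#' @param n number of genes to return (default 2000; capped at the number
#'   of non-constant genes).
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of gene names, most variable first.
#' @export
select_variable_genes <- function(counts, n = 2000, loess_span = 0.3) {
  m <- if (inherits(counts, "v1_counts")) counts$counts else counts
  nc <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * nc / (nc - 1)
  usable <- which(v > 0 & mu > 0)
  if (!length(usable)) stop("no non-constant genes")
  fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                      span = loess_span, degree = 2)
  sd_exp <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(nc)
  ## standardized variance per gene, computed sparse-aware:
  ## sum over cells of min(clip, (x - mu)/sd)^2, zeros contributing the
  ## clipped standardized value of 0.
  msub <- m[usable, , drop = FALSE]
  msub <- methods::as(msub, "CsparseMatrix")
  mt <- Matrix::t(msub)                    # cells x genes; col slices = genes
  counts_per_gene <- diff(mt@p)
  gene_of <- rep.int(seq_along(usable), counts_per_gene)
  z <- (mt@x - mu[usable][gene_of]) / sd_exp[gene_of]
  z <- pmin(z, clip)
  z <- pmax(z, -clip)
  sum_nz <- tapply(z^2, factor(gene_of, levels = seq_along(usable)), sum,
                   default = 0)
  z0 <- pmax(pmin(-mu[usable] / sd_exp, clip), -clip)
  n_zero <- nc - counts_per_gene
  std_var <- (as.numeric(sum_nz) + n_zero * z0^2) / (nc - 1)
  ord <- usable[order(std_var, decreasing = TRUE)]
  rownames(m)[utils::head(ord, n)]
}

#' Choose the number of principal components from percent variances
#'
#' Two criteria are evaluated on the (nonincreasing) percent-variance
#' vector: (A) the first component index k at which the cumulative percent
#' variance exceeds 90 and the individual percent variance is below 5;
#' (B) one past the last index i at which the drop in percent variance
#' between components i and i+1 exceeds 0.1. The smaller of the two is
#' returned. If criterion A is never met the full length is used with a
#' warning.
#'
#' @param percent_variances numeric vector of percent variance explained per
#'   component, descending.
#' @return integer count of components, with attributes `criterion_a` and
#'   `criterion_b` carrying both intermediate answers.
#' @export
find_pc <- function(percent_variances) {
  pv <- percent_variances
  stopifnot(length(pv) >= 1, all(pv >= 0))
  cum <- cumsum(pv)
  a_hits <- which(cum > 90 & pv < 5)
  a <- if (length(a_hits)) a_hits[1] else {
    warning("cumulative>90% & individual<5% never met; using all components")
    length(pv)
  }
  gaps <- which(diff(pv) < -0.1)           # drop in percent variation > 0.1
  ## with no qualifying drop, criterion B does not bind
  b <- if (length(gaps)) max(gaps) + 1L else NA_integer_
  structure(min(a, b, na.rm = TRUE), criterion_a = a, criterion_b = b)
}

#' PCA over variable genes with automatic component count
#'
#' Scales each variable gene to unit variance (values clipped at 10) and
#' runs truncated PCA. The retained component count comes from [find_pc()]
#' applied to the percent variance of the computed components.
#'
#' @param norm normalized gene x nucleus matrix from [lognormalize()].
#' @param var_genes character vector of genes to use (default: all rows).
#' @param n_pcs number of components to compute (default 30).
#' @param clip cap for scaled values.
#' @param seed integer seed for the truncated solver.
#' @return list of class `pc_result`: `scores` (nuclei x components),
#'   `percent_variance`, `chosen_npc`, `rotation`, `center`, `scale`,
#'   `genes`.
#' @export
run_pca <- function(norm, var_genes = rownames(norm), n_pcs = 30,
                    clip = 10, seed = 0L) {
  sub <- norm[var_genes, , drop = FALSE]
  n_pcs <- min(n_pcs, nrow(sub) - 1, ncol(sub) - 1)
  x <- Matrix::t(sub)
  mu <- Matrix::colMeans(x)
  sdv <- sqrt(pmax(Matrix::colMeans(x^2) - mu^2, 0) *
                nrow(x) / (nrow(x) - 1))
  keep <- sdv > 0
  xd <- as.matrix(x[, keep, drop = FALSE])
  xd <- scale(xd, center = mu[keep], scale = sdv[keep])
  xd[xd > clip] <- clip
  xd[xd < -clip] <- -clip
  set.seed(seed)
  sv <- if (n_pcs < min(dim(xd)) / 2) irlba::irlba(xd, nv = n_pcs)
  else {
    s <- svd(xd, nu = n_pcs, nv = n_pcs)   # tiny matrices: exact SVD
    list(u = s$u, d = s$d[seq_len(n_pcs)], v = s$v)
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  ## percentages of the computed spectrum (the elbow-rule convention):
  ## they sum to 100 over the retained components
  pv <- 100 * sv$d^2 / sum(sv$d^2)
  rownames(scores) <- rownames(x)
  npc <- find_pc(pv)
  structure(list(scores = scores, percent_variance = pv,
                 chosen_npc = as.integer(npc),
                 criterion_a = attr(npc, "criterion_a"),
                 criterion_b = attr(npc, "criterion_b"),
                 rotation = sv$v, center = mu[keep], scale = sdv[keep],
                 genes = var_genes[keep]), class = "pc_result")
}

#' Align samples in PC space by mutual-nearest-neighbour shifts
#'
#' Contract-level batch alignment: each non-reference sample is translated
#' by the mean displacement of its mutual nearest neighbours in the
#' reference sample, computed in PC space. With fewer than two samples the
#' representation passes through unchanged. The exact algorithm is
#' deliberately simple; the contract is that aligned replicates of the same
#' condition mix better (higher sample-iLISI) than unaligned ones.
#'
#' @param scores nuclei x components matrix (e.g. `pc$scores`).
#' @param sample character/factor of sample labels per nucleus.
#' @param reference reference sample name (default: first level).
#' @param k neighbours per direction for the mutual-NN search.
#' @return matrix of the same shape as `scores` with per-sample shifts
#'   applied.
#' @export
align_batches <- function(scores, sample, reference = NULL, k = 20) {
  sample <- as.character(sample)
  samples <- unique(sample)
  if (length(samples) < 2) return(scores)
  if (is.null(reference)) reference <- samples[1]
  stopifnot(reference %in% samples)
  ref <- scores[sample == reference, , drop = FALSE]
  out <- scores
  for (s in setdiff(samples, reference)) {
    idx <- which(sample == s)
    qry <- scores[idx, , drop = FALSE]
    k_use <- min(k, nrow(ref), nrow(qry))
    ab <- RANN::nn2(ref, qry, k = k_use)$nn.idx      # query -> ref
    ba <- RANN::nn2(qry, ref, k = k_use)$nn.idx      # ref -> query
    pairs <- which(matrix(mapply(function(q, r) q %in% ba[r, ],
                                 rep(seq_len(nrow(qry)), k_use),
                                 as.vector(ab)),
                          nrow = nrow(qry)), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    q_i <- pairs[, 1]
    r_i <- ab[pairs]
    shift <- colMeans(ref[r_i, , drop = FALSE]) -
      colMeans(qry[q_i, , drop = FALSE])
    out[idx, ] <- sweep(qry, 2, shift, "+")
  }
  out
}

#' Graph-based clustering of nuclei
#'
#' Builds a k-nearest-neighbour graph in the supplied representation and
#' runs modularity-based (Louvain) community detection at the given
#' resolution. Labels are contiguous integers from 0, ordered by decreasing
#' cluster size. The 2-D embedding returned for plotting and neighbourhood
#' scores is the first two columns of the representation.
#'
#' @param representation nuclei x dims matrix (PC scores, possibly aligned).
#' @param resolution Louvain resolution parameter (igraph scaling; larger
#'   values produce more clusters).
#' @param k neighbours for the graph (default 20).
#' @param seed integer seed; fixes the community detection.
#' @return list of class `cluster_result`: `clusters` (integer per nucleus),
#'   `resolution`, `k`, `embedding` (nuclei x 2).
#' @export
cluster_nuclei <- function(representation, resolution = 1, k = 20,
                           seed = 0L) {
  n <- nrow(representation)
  k_use <- min(k, n - 1)
  degenerate <- n >= 1 &&
    all(apply(representation, 2, function(v) diff(range(v))) < 1e-12)
  if (k_use < 1 || n < 3 || degenerate) {
    cl <- rep(0L, n)
  } else {
    nn <- RANN::nn2(representation, k = k_use + 1)$nn.idx[, -1, drop = FALSE]
    edges <- cbind(rep(seq_len(n), k_use), as.vector(nn))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    raw <- igraph::membership(comm)
    sizes <- sort(table(raw), decreasing = TRUE)
    cl <- as.integer(match(raw, names(sizes))) - 1L
  }
  structure(list(clusters = cl, resolution = resolution, k = k_use,
                 embedding = representation[, 1:min(2, ncol(representation)),
                                            drop = FALSE]),
            class = "cluster_result")
}
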