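#' Default non-V1 marker panels for negative selection
#'
#' Panels of genes marking contaminant populations (glia, microglia, motor
#' neurons, non-V1 interneurons). These ship as illustrative working panels
#' matching the generator's contaminant populations; real analyses supply
#' their own panels as a two-column data.frame (panel, gene).
#'
#' @return named list of character vectors.
#' @export
default_marker_panels <- function() {
  lapply(default_contaminants(), `[[`, "genes")
}

#' Per-cluster marker-panel z-scores
#'
#' For each panel, the mean normalized expression of its genes is averaged
#' within each cluster and z-scored across clusters. A cluster whose z-score
#' is high for a contaminant panel is a candidate for removal.
#'
#' @param norm normalized gene x nucleus matrix.
#' @param clusters integer/character cluster label per nucleus.
#' @param panels named list of gene vectors (see [default_marker_panels()]).
#'   Genes absent from the matrix are dropped with a message; a panel with
#'   no genes present is an error.
#' @return matrix of z-scores, clusters x panels.
#' @export
score_panels <- function(norm, clusters, panels) {
  cl <- as.character(clusters)
  levels <- sort(unique(cl))
  z <- matrix(NA_real_, length(levels), length(panels),
              dimnames = list(levels, names(panels)))
  means <- z
  for (p in names(panels)) {
    genes <- intersect(panels[[p]], rownames(norm))
    if (!length(genes))
      stop("panel ", p, " has no genes present in the matrix")
    if (length(genes) < length(panels[[p]]))
      message("panel ", p, ": ",
              length(panels[[p]]) - length(genes), " gene(s) missing")
    panel_mean <- Matrix::colMeans(norm[genes, , drop = FALSE])
    cluster_mean <- tapply(panel_mean, factor(cl, levels = levels), mean)
    mu <- mean(cluster_mean)
    sdv <- stats::sd(cluster_mean)
    z[, p] <- if (sdv > 0) (cluster_mean - mu) / sdv else 0
    means[, p] <- cluster_mean
  }
  attr(z, "means") <- means
  z
}

#' Iterative negative selection of contaminant clusters
#'
#' Repeats rounds of normalize -> variable genes -> PCA (component count by
#' [find_pc()]) -> graph clustering, flags clusters whose z-score for any
#' contaminant panel exceeds `z_threshold` or whose median mitochondrial
#' fraction breaches the QC cut, removes the flagged nuclei, and stops when
#' a round removes nothing or `max_rounds` is reached. The returned log is
#' an auditable record of every removal and the rule that triggered it.
#'
#' @param x a post-QC [v1_counts] object.
#' @param panels named list of contaminant gene panels.
#' @param z_threshold panel z-score above which a cluster is flagged
#'   (default 2).
#' @param min_expr absolute floor: a cluster is only flagged for a panel
#'   when its mean panel expression also exceeds this value (log-normalized
#'   units; default 0.1). Guards against flagging relative outliers among
#'   clusters that barely express the panel at all.
#' @param max_mito median mitochondrial fraction above which a cluster is
#'   flagged (default 0.025).
#' @param max_rounds maximum number of rounds (default 10).
#' @param resolution,k,n_var clustering parameters per round.
#' @param seed integer seed (clustering determinism).
#' @return list of class `neg_selection`: `counts` (retained nuclei),
#'   `retained` (barcodes), `log` (data.frame: round, cluster, panel,
#'   z, n_removed, rule), `rounds`.
#' @export
negative_selection <- function(x, panels = default_marker_panels(),
                               z_threshold = 2, min_expr = 0.1,
                               max_mito = 0.025,
                               max_rounds = 10, resolution = 1, k = 20,
                               n_var = 2000, seed = 0L) {
  stopifnot(inherits(x, "v1_counts"))
  present <- vapply(panels, function(g)
    length(intersect(g, rownames(x$counts))) > 0, logical(1))
  if (!all(present))
    message("panel(s) with no genes present skipped: ",
            paste(names(panels)[!present], collapse = ", "))
  panels <- panels[present]
  if (!length(panels)) stop("no usable marker panels")
  log_rows <- list()
  cur <- x
  round_i <- 0
  repeat {
    round_i <- round_i + 1
    norm <- lognormalize(cur)
    vg <- select_variable_genes(cur, n = min(n_var, nrow(norm)))
    pc <- run_pca(norm, vg, seed = seed)
    rep_use <- pc$scores[, seq_len(pc$chosen_npc), drop = FALSE]
    clr <- cluster_nuclei(rep_use, resolution = resolution, k = k,
                          seed = seed)
    z <- score_panels(norm, clr$clusters, panels)
    panel_means <- attr(z, "means")
    qc <- compute_qc(cur)
    med_mito <- tapply(qc$mito_frac,
                       factor(as.character(clr$clusters),
                              levels = rownames(z)), stats::median)
    flagged <- character(0)
    for (clu in rownames(z)) {
      hits <- which(z[clu, ] > z_threshold &
                      panel_means[clu, ] > min_expr)
      if (length(hits)) {
        p <- names(hits)[which.max(z[clu, hits])]
        flagged <- c(flagged, clu)
        log_rows[[length(log_rows) + 1]] <- data.frame(
          round = round_i, cluster = clu, panel = p, z = z[clu, p],
          n_removed = sum(as.character(clr$clusters) == clu),
          rule = "panel_z", stringsAsFactors = FALSE)
      } else if (is.finite(med_mito[clu]) && med_mito[clu] > max_mito) {
        flagged <- c(flagged, clu)
        log_rows[[length(log_rows) + 1]] <- data.frame(
          round = round_i, cluster = clu, panel = NA_character_,
          z = NA_real_,
          n_removed = sum(as.character(clr$clusters) == clu),
          rule = "median_mito", stringsAsFactors = FALSE)
      }
    }
    if (!length(flagged) || round_i >= max_rounds) break
    keep <- !(as.character(clr$clusters) %in% flagged)
    if (!any(keep)) stop("negative selection removed every nucleus")
    cur <- subset_counts(cur, nuclei = keep)
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(round = integer(0), cluster = character(0),
               panel = character(0), z = numeric(0),
               n_removed = integer(0), rule = character(0))
  structure(list(counts = cur, retained = colnames(cur$counts),
                 log = log_df, rounds = round_i),
            class = "neg_selection")
}

#' Reference-based label transfer with prediction scores
#'
#' Projects query nuclei into the reference's PC space over shared genes and
#' scores each query nucleus by the Gaussian-kernel-weighted fraction of
#' each reference label among its k nearest reference cells. Scores form an
#' exact probability vector per nucleus. Zero-distance reference matches
#' dominate (the kernel limit), so a query duplicating a reference cell
#' inherits its label with score 1. Ties in the argmax are broken by
#' lexicographic label order.
#'
#' @param query_norm normalized gene x nucleus matrix for the query.
#' @param ref_norm normalized gene x cell matrix for the reference.
#' @param ref_labels character label per reference cell (must include the
#'   target class, e.g. "V1").
#' @param k neighbours (default 30).
#' @param n_pcs reference PC count (default 30).
#' @param min_shared minimum shared-gene count (default 100).
#' @param n_var variable genes used for the reference PCA.
#' @param seed integer seed for the truncated PCA solver.
#' @return list of class `prediction_score`: `scores` (nuclei x labels,
#'   rows sum to 1), `label` (argmax per nucleus).
#' @export
transfer_labels <- function(query_norm, ref_norm, ref_labels, k = 30,
                            n_pcs = 30, min_shared = 100, n_var = 2000,
                            seed = 0L) {
  shared <- intersect(rownames(query_norm), rownames(ref_norm))
  if (!length(shared)) stop("no shared genes between query and reference")
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes (< ", min_shared, ")")
  stopifnot(length(ref_labels) == ncol(ref_norm))
  ref <- ref_norm[shared, , drop = FALSE]
  qry <- query_norm[shared, , drop = FALSE]
  vg <- select_variable_genes(expm1_counts(ref), n = min(n_var, length(shared)))
  pc <- run_pca(ref, vg, n_pcs = n_pcs, seed = seed)
  proj <- project_pca(qry, pc)
  labels <- sort(unique(ref_labels))
  k_use <- min(k, ncol(ref))
  nn <- RANN::nn2(pc$scores, proj, k = k_use)
  scores <- matrix(0, nrow(proj), length(labels),
                   dimnames = list(rownames(proj), labels))
  d <- nn$nn.dists
  sigma <- pmax(apply(d, 1, stats::median), .Machine$double.eps)
  w <- exp(-(d / sigma)^2 / 2)
  exact <- d < 1e-8
  has_exact <- rowSums(exact) > 0
  w[has_exact, ] <- exact[has_exact, , drop = FALSE]  # kernel limit
  lab_mat <- matrix(ref_labels[nn$nn.idx], nrow = nrow(proj))
  for (lb in labels)
    scores[, lb] <- rowSums(w * (lab_mat == lb))
  scores <- scores / rowSums(scores)
  structure(list(scores = scores,
                 label = labels[max.col(scores, ties.method = "first")]),
            class = "prediction_score")
}

# Undo log1p normalization back to a count-like scale (for vst ranking of a
# reference supplied as normalized values).
expm1_counts <- function(norm) {
  m <- norm
  m@x <- expm1(m@x)
  m
}

# Project new nuclei onto an existing pc_result's component space.
project_pca <- function(norm, pc, clip = 10) {
  x <- Matrix::t(norm[pc$genes, , drop = FALSE])
  xd <- scale(as.matrix(x), center = pc$center, scale = pc$scale)
  xd[xd > clip] <- clip
  xd[xd < -clip] <- -clip
  out <- xd %*% pc$rotation
  rownames(out) <- rownames(x)
  out
}

#' Final positive selection of V1 nuclei
#'
#' A nucleus is retained iff its argmax label is `target` and its target
#' score is at least `threshold` (a score of exactly 0.49 at the default
#' 0.5 threshold is excluded).
#'
#' @param pred a `prediction_score` from [transfer_labels()].
#' @param threshold minimum target score (default 0.5).
#' @param target class to keep (default "V1").
#' @return logical keep-mask per query nucleus.
#' @export
select_v1 <- function(pred, threshold = 0.5, target = "V1") {
  stopifnot(inherits(pred, "prediction_score"))
  if (!target %in% colnames(pred$scores))
    stop("reference labels do not include ", target)
  pred$label == target & pred$scores[, target] >= threshold
}
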