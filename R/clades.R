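#' Per-nucleus clade marker thresholds
#'
#' Log-normalized expression cutoffs above which a nucleus is called
#' positive for a clade marker: Foxp2 > 2.8, Sp8 > 0.8, Pou6f2 > 2.6,
#' Chrna2 > 1.1 (Chrna2 proxies the MafA/Calbindin clade). The comparison
#' is strict.
#'
#' @param Foxp2,Sp8,Pou6f2,Chrna2 override any threshold.
#' @param Rnf220 optional per-nucleus threshold for the fifth clade marker
#'   (`NA` disables per-nucleus Rnf220 calls; the Rnf220 clade is assigned
#'   at cluster level from z-scores).
#' @return named numeric vector of class `clade_thresholds`.
#' @export
clade_thresholds <- function(Foxp2 = 2.8, Sp8 = 0.8, Pou6f2 = 2.6,
                             Chrna2 = 1.1, Rnf220 = NA) {
  out <- c(Foxp2 = Foxp2, Sp8 = Sp8, Pou6f2 = Pou6f2, Chrna2 = Chrna2,
           Rnf220 = Rnf220)
  if (any(out[!is.na(out)] <= 0)) stop("thresholds must be positive")
  structure(out[!is.na(out)], class = "clade_thresholds")
}

#' Call per-nucleus marker positivity
#'
#' A nucleus is positive for a marker iff its log-normalized expression
#' strictly exceeds the marker's threshold; a value exactly at the cutoff is
#' negative. Calls are made on the merged log-normalized matrix, not on
#' batch-corrected values.
#'
#' @param norm normalized gene x nucleus matrix containing every marker.
#' @param thresholds a [clade_thresholds()].
#' @return logical matrix, nuclei x markers.
#' @export
call_marker_positive <- function(norm, thresholds = clade_thresholds()) {
  markers <- names(thresholds)
  missing <- setdiff(markers, rownames(norm))
  if (length(missing))
    stop("marker gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  out <- sapply(markers, function(g)
    as.vector(norm[g, ]) > thresholds[[g]])
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, markers))
  rownames(out) <- colnames(norm)
  out
}

#' Cross-cluster marker z-scores
#'
#' Averages each marker's normalized expression over the nuclei of each
#' cluster, then scales across clusters (mean 0, sd 1 per marker).
#'
#' @param norm normalized gene x nucleus matrix.
#' @param clusters cluster label per nucleus (at least two clusters).
#' @param markers marker genes (default the four primary clade markers plus
#'   Rnf220 when present in the matrix).
#' @return numeric matrix, clusters x markers.
#' @export
cluster_clade_zscores <- function(norm, clusters,
                                  markers = intersect(
                                    c("Foxp2", "Sp8", "Pou6f2", "Chrna2",
                                      "Rnf220"), rownames(norm))) {
  cl <- factor(as.character(clusters))
  if (nlevels(cl) < 2)
    stop("z-scores need at least two clusters")
  missing <- setdiff(markers, rownames(norm))
  if (length(missing))
    stop("marker gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  means <- sapply(markers, function(g)
    tapply(as.vector(norm[g, ]), cl, mean))
  scale(means)[, , drop = FALSE]
}

#' Assign a clade to every cluster from marker z-scores
#'
#' Each cluster is assigned to the marker with a positive z-score; when more
#' than one z-score is positive the highest wins (the documented tie rule).
#' A cluster with no positive primary z-score is assigned to the Rnf220
#' clade when its Rnf220 z-score is positive, and is otherwise unassigned.
#' Chrna2 stands for the MafA/Calb clade in the output labels.
#'
#' @param z clusters x markers z-score matrix over the four primary markers
#'   (columns Foxp2, Sp8, Pou6f2, Chrna2).
#' @param rnf220_z optional named numeric vector of Rnf220 z-scores per
#'   cluster (may also be a column of `z`).
#' @return named character vector: clade per cluster, levels Foxp2, Sp8,
#'   Pou6f2, MafA/Calb, Rnf220, unassigned.
#' @export
assign_clades <- function(z, rnf220_z = NULL) {
  primary <- c("Foxp2", "Sp8", "Pou6f2", "Chrna2")
  if (is.null(rnf220_z) && "Rnf220" %in% colnames(z))
    rnf220_z <- z[, "Rnf220"]
  z <- z[, intersect(primary, colnames(z)), drop = FALSE]
  stopifnot(ncol(z) >= 1)
  out <- apply(z, 1, function(row) {
    pos <- row[row > 0]
    if (length(pos)) names(pos)[which.max(pos)] else NA_character_
  })
  if (!is.null(rnf220_z)) {
    fallback <- is.na(out) & rnf220_z[rownames(z)] > 0
    out[fallback] <- "Rnf220"
  }
  out[is.na(out)] <- "unassigned"
  out[out == "Chrna2"] <- "MafA/Calb"
  names(out) <- rownames(z)
  out
}

#' Count nuclei co-expressing two or more clade markers
#'
#' @param calls logical nuclei x markers matrix from
#'   [call_marker_positive()], restricted to the four primary clade markers
#'   if wider.
#' @return integer count of nuclei positive for at least two markers.
#' @export
count_coexpressing <- function(calls) {
  primary <- intersect(c("Foxp2", "Sp8", "Pou6f2", "Chrna2"),
                       colnames(calls))
  sum(rowSums(calls[, primary, drop = FALSE]) >= 2)
}

#' Clade proportions per replicate
#'
#' Fraction of nuclei falling in the clusters assigned to each clade,
#' computed per replicate and summarized as mean +/- SEM across replicates.
#' Fractions (including "unassigned") sum to 1 within each replicate.
#'
#' @param clusters cluster label per nucleus.
#' @param clade_map named character vector from [assign_clades()].
#' @param replicate replicate label per nucleus (a single label gives
#'   SEM = NA).
#' @return list with `per_replicate` (replicates x clades matrix of
#'   fractions) and `summary` (data.frame: clade, mean, sem).
#' @export
clade_proportions <- function(clusters, clade_map, replicate = "R1") {
  cl <- as.character(clusters)
  if (length(replicate) == 1) replicate <- rep(replicate, length(cl))
  clade <- clade_map[cl]
  clade[is.na(clade)] <- "unassigned"
  clades <- unique(c(unname(clade_map), "unassigned"))
  tab <- table(replicate = replicate,
               clade = factor(clade, levels = clades))
  frac <- sweep(tab, 1, rowSums(tab), "/")
  mean_f <- colMeans(frac)
  sem <- apply(frac, 2, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  list(per_replicate = unclass(frac),
       summary = data.frame(clade = clades, mean = as.numeric(mean_f),
                            sem = as.numeric(sem),
                            stringsAsFactors = FALSE))
}
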