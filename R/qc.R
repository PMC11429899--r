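#' Per-nucleus quality-control metrics
#'
#' Computes, for every nucleus, the total UMI count, the number of detected
#' genes and the fraction of counts derived from mitochondrial genes. An
#' all-zero nucleus has mitochondrial fraction 0 by convention.
#'
#' @param x a [v1_counts] object.
#' @param mito_genes character vector of mitochondrial gene names. The
#'   default takes every gene whose name starts with "mt-". Every named gene
#'   must exist in the matrix.
#' @return data.frame (one row per nucleus): `barcode`, `sample`,
#'   `total_umi`, `n_genes`, `mito_frac`.
#' @export
compute_qc <- function(x, mito_genes = NULL) {
  stopifnot(inherits(x, "v1_counts"))
  m <- x$counts
  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(m), value = TRUE)
  missing <- setdiff(mito_genes, rownames(m))
  if (length(missing))
    stop("unknown mitochondrial genes: ", paste(missing, collapse = ", "))
  total <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito <- if (length(mito_genes))
    Matrix::colSums(m[mito_genes, , drop = FALSE]) else rep(0, ncol(m))
  frac <- ifelse(total > 0, mito / total, 0)
  data.frame(barcode = colnames(m), sample = x$meta$sample,
             total_umi = as.numeric(total), n_genes = as.numeric(ngene),
             mito_frac = frac, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Default quality-control thresholds
#'
#' Minimum 1000 UMIs per nucleus, at most 2.5% mitochondrial transcripts,
#' per-sample fences at median +/- 3 unscaled median absolute deviations on
#' both UMI and gene counts, and a minimum of 10 nuclei per retained gene.
#'
#' @param min_umi,max_mito,n_mads,min_cells_per_gene override any cutoff.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 1000, max_mito = 0.025, n_mads = 3,
                          min_cells_per_gene = 10) {
  stopifnot(min_umi > 0, max_mito > 0, n_mads > 0, min_cells_per_gene > 0)
  structure(list(min_umi = min_umi, max_mito = max_mito, n_mads = n_mads,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

# Unscaled median absolute deviation: median(|x - median(x)|). The 1.4826
# normal-consistency factor is deliberately not applied; fences operate on
# raw UMI/gene counts.
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

#' Nucleus keep-mask from QC metrics
#'
#' A nucleus is kept iff it has at least `min_umi` UMIs, at most `max_mito`
#' mitochondrial fraction and, within its sample, both its UMI and gene
#' counts lie within median +/- `n_mads` * MAD (unscaled, computed on the
#' raw values). Nuclei above the upper UMI fence double as putative
#' doublets; no separate doublet detector is applied. A single-nucleus
#' sample has no defined MAD: its nucleus is kept with a warning.
#'
#' @param qc data.frame from [compute_qc()].
#' @param thr a [qc_thresholds()].
#' @return logical keep-mask aligned with `qc` rows.
#' @export
filter_nuclei <- function(qc, thr = qc_thresholds()) {
  stopifnot(all(c("sample", "total_umi", "n_genes", "mito_frac") %in%
                  names(qc)))
  keep <- qc$total_umi >= thr$min_umi & qc$mito_frac <= thr$max_mito
  for (s in unique(qc$sample)) {
    idx <- which(qc$sample == s)
    if (length(idx) == 1) {
      warning("sample ", s, " has a single nucleus; MAD fences skipped")
      next
    }
    for (col in c("total_umi", "n_genes")) {
      v <- qc[[col]][idx]
      ctr <- stats::median(v)
      fence <- thr$n_mads * raw_mad(v)
      keep[idx] <- keep[idx] & v >= ctr - fence & v <= ctr + fence
    }
  }
  keep
}

#' Gene keep-mask: detected in at least `min_cells` nuclei
#'
#' @param x a [v1_counts] object.
#' @param min_cells minimum number of nuclei with a nonzero count (default
#'   10; a gene seen in exactly 10 nuclei is kept).
#' @return logical keep-mask over genes.
#' @export
filter_genes <- function(x, min_cells = 10) {
  stopifnot(inherits(x, "v1_counts"))
  as.vector(Matrix::rowSums(x$counts > 0) >= min_cells)
}

#' Apply both QC filters to a count object
#'
#' Convenience wrapper: computes metrics, drops failing nuclei, then drops
#' rarely detected genes. Filtering is idempotent.
#'
#' @param x a [v1_counts] object.
#' @param thr a [qc_thresholds()].
#' @param mito_genes passed to [compute_qc()].
#' @return list with the filtered `counts` ([v1_counts]), the `qc` table and
#'   the two masks (`keep_nuclei`, `keep_genes`).
#' @export
apply_qc <- function(x, thr = qc_thresholds(), mito_genes = NULL) {
  qc <- compute_qc(x, mito_genes)
  keep_n <- filter_nuclei(qc, thr)
  if (!any(keep_n)) stop("QC removed every nucleus")
  kept <- subset_counts(x, nuclei = keep_n)
  keep_g <- filter_genes(kept, thr$min_cells_per_gene)
  list(counts = subset_counts(kept, genes = keep_g), qc = qc,
       keep_nuclei = keep_n, keep_genes = keep_g)
}
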