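#' Raw UMI count container
#'
#' Bundles a sparse gene x nucleus matrix of raw unique-molecular-identifier
#' (UMI) counts with per-nucleus metadata (sample, age, genotype, replicate).
#' This is the object every pipeline stage consumes or returns; rows are
#' genes, columns are nuclei, and `meta` has one row per column of `counts`.
#'
#' @param counts sparse (or dense, coerced) nonnegative integer matrix with
#'   gene symbols as rownames and nucleus barcodes as colnames.
#' @param meta data.frame with one row per nucleus; must contain a `sample`
#'   column. Rownames are set to the barcodes.
#' @return An object of class `v1_counts` (a list with elements `counts` and
#'   `meta`).
#' @export
v1_counts <- function(counts, meta) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)) || (ncol(counts) > 0 &&
                                    is.null(colnames(counts))))
    stop("counts must carry gene rownames and barcode colnames")
  if (is.null(colnames(counts)))
    colnames(counts) <- character(0)
  meta <- as.data.frame(meta)
  if (nrow(meta) != ncol(counts))
    stop("meta must have one row per nucleus (", ncol(counts), ")")
  if (!"sample" %in% names(meta)) stop("meta must contain a 'sample' column")
  rownames(meta) <- colnames(counts)
  structure(list(counts = counts, meta = meta), class = "v1_counts")
}

#' @export
print.v1_counts <- function(x, ...) {
  cat("v1_counts: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " nuclei, ", length(unique(x$meta$sample)), " sample(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.v1_counts <- function(x) dim(x$counts)

#' Subset a count object by gene and/or nucleus
#'
#' @param x `v1_counts` object.
#' @param genes,nuclei index vectors (logical, integer or names); `NULL`
#'   keeps everything.
#' @return A `v1_counts` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, nuclei = NULL) {
  stopifnot(inherits(x, "v1_counts"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(nuclei)) m <- m[, nuclei, drop = FALSE]
  v1_counts(m, x$meta[colnames(m), , drop = FALSE])
}

#' Read a Matrix Market count directory
#'
#' Expects the conventional triplet layout: `matrix.mtx` (genes x nuclei),
#' `genes.tsv` (one gene symbol per line), and `metadata.tsv` (tab-separated,
#' header row, first column the nucleus barcode, remaining columns metadata;
#' must include `sample`).
#'
#' @param path directory containing the three files.
#' @return A [v1_counts] object.
#' @export
read_counts <- function(path) {
  f <- function(name) file.path(path, name)
  for (name in c("matrix.mtx", "genes.tsv", "metadata.tsv"))
    if (!file.exists(f(name))) stop("missing ", name, " in ", path)
  m <- Matrix::readMM(f("matrix.mtx"))
  genes <- readLines(f("genes.tsv"))
  meta <- utils::read.delim(f("metadata.tsv"), stringsAsFactors = FALSE)
  if (length(genes) != nrow(m))
    stop("genes.tsv has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  if (nrow(meta) != ncol(m))
    stop("metadata.tsv has ", nrow(meta), " rows but matrix has ",
         ncol(m), " columns")
  rownames(m) <- genes
  colnames(m) <- meta[[1]]
  v1_counts(m, meta[, -1, drop = FALSE])
}

#' Write a count object as Matrix Market + TSV
#'
#' Inverse of [read_counts()]; the round trip is lossless for integer counts
#' and metadata columns.
#'
#' @param x `v1_counts` object.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "v1_counts"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(path, "genes.tsv"))
  bc <- colnames(x$counts)
  if (is.null(bc)) bc <- character(0)      # 0-column matrix stores NULL
  meta <- data.frame(barcode = bc, x$meta,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
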