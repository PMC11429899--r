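#' Normalize neuron positions to the standardized hemisection
#'
#' Rescales raw coordinates (central canal at the origin, +x lateral, -y
#' ventral, in um) so that every section's lateral extent maps to 650 um
#' and its ventral extent to 400 um: x' = x * 650 / L, y' = y * 400 / V.
#' The ventral scale factor is also applied to dorsal (positive y) points;
#' the dorsal extent is not separately standardized. Already-standardized
#' sections (L = 650, V = 400) pass through unchanged.
#'
#' @param points data.frame with columns `section`, `x`, `y` (um).
#' @param extents data.frame with columns `section`, `L` (central canal to
#'   lateral boundary, um) and `V` (central canal to ventral boundary, um);
#'   both strictly positive.
#' @return `points` with standardized `x`, `y` (extra columns preserved).
#' @export
normalize_position <- function(points, extents) {
  stopifnot(all(c("section", "x", "y") %in% names(points)),
            all(c("section", "L", "V") %in% names(extents)))
  if (any(extents$L <= 0) || any(extents$V <= 0))
    stop("section extents must be positive")
  i <- match(points$section, extents$section)
  if (anyNA(i)) stop("sections without extents: ",
                     paste(unique(points$section[is.na(i)]), collapse = ", "))
  points$x <- points$x * 650 / extents$L[i]
  points$y <- points$y * 400 / extents$V[i]
  points
}

#' Kernel density surface over neuron positions
#'
#' Two-dimensional Gaussian kernel density on a regular grid (the surface
#' from which position contours are drawn). Bandwidths default to the
#' normal-reference rule per axis; the returned density integrates to ~1
#' for interior distributions.
#'
#' @param points data.frame with `x`, `y` (>= 2 points).
#' @param bandwidth numeric length-2 bandwidth (x, y); default
#'   normal-reference rule.
#' @param grid_n grid points per axis (default 100).
#' @param lims c(xmin, xmax, ymin, ymax); default expands the data range by
#'   three bandwidths.
#' @return list as from [MASS::kde2d()]: `x`, `y`, `z`.
#' @export
density_grid <- function(points, bandwidth = NULL, grid_n = 100,
                         lims = NULL) {
  stopifnot(nrow(points) >= 2)
  if (is.null(bandwidth)) {
    bw1 <- MASS::bandwidth.nrd(points$x)
    bw2 <- MASS::bandwidth.nrd(points$y)
    if (bw1 <= 0) bw1 <- 1
    if (bw2 <= 0) bw2 <- 1
    bandwidth <- c(bw1, bw2)
  }
  if (is.null(lims))
    lims <- c(range(points$x) + c(-3, 3) * bandwidth[1],
              range(points$y) + c(-3, 3) * bandwidth[2])
  MASS::kde2d(points$x, points$y, h = bandwidth, n = grid_n, lims = lims)
}

# Quadrant-difference statistic with one sample's points as origins:
# max over origins and the four open quadrants of |F_A - F_B|.
# Vectorized over origins: outer comparisons give point-by-origin masks.
ff_half <- function(origins, ax, ay, bx, by) {
  ox <- origins[, 1]; oy <- origins[, 2]
  na <- length(ax); nb <- length(bx)
  agt <- outer(ax, ox, ">"); alt <- outer(ax, ox, "<")
  aup <- outer(ay, oy, ">"); adn <- outer(ay, oy, "<")
  bgt <- outer(bx, ox, ">"); blt <- outer(bx, ox, "<")
  bup <- outer(by, oy, ">"); bdn <- outer(by, oy, "<")
  d <- rbind(
    abs(colSums(agt & aup) / na - colSums(bgt & bup) / nb),
    abs(colSums(alt & aup) / na - colSums(blt & bup) / nb),
    abs(colSums(alt & adn) / na - colSums(blt & bdn) / nb),
    abs(colSums(agt & adn) / na - colSums(bgt & bdn) / nb)
  )
  max(d)
}

# Fasano-Franceschini statistic: average of the two per-sample maxima.
ks2d_statistic <- function(ax, ay, bx, by) {
  da <- ff_half(cbind(ax, ay), ax, ay, bx, by)
  db <- ff_half(cbind(bx, by), ax, ay, bx, by)
  (da + db) / 2
}

#' Two-dimensional Kolmogorov-Smirnov test (Fasano-Franceschini)
#'
#' For each data point taken as origin, the two samples' empirical
#' fractions in the four open quadrants are compared; D is the average of
#' the two per-sample maxima of |F_A - F_B|. The p-value comes from
#' label permutation of the pooled points (`n_perm` reps, seeded), giving
#' p in [1/(n_perm+1), 1]. D is 0 for identical point multisets and 1 when
#' the supports occupy disjoint quadrants, and is invariant to any shared
#' affine rescaling of both samples.
#'
#' @param a,b data.frames with `x`, `y` columns (warns below 10 points).
#' @param n_perm permutation count (default 1000).
#' @param seed integer seed for the permutations.
#' @return list of class `ks2d_result`: `D`, `p`, `n` (c(nA, nB)),
#'   `n_perm`.
#' @export
ks2d <- function(a, b, n_perm = 1000, seed = 0L) {
  ax <- a$x; ay <- a$y; bx <- b$x; by <- b$y
  na <- length(ax); nb <- length(bx)
  if (na < 10 || nb < 10)
    warning("fewer than 10 points in a sample; D is unstable")
  D <- ks2d_statistic(ax, ay, bx, by)
  set.seed(seed)
  px <- c(ax, bx); py <- c(ay, by)
  exceed <- 0
  for (r in seq_len(n_perm)) {
    idx <- sample.int(na + nb, na)
    Dp <- ks2d_statistic(px[idx], py[idx], px[-idx], py[-idx])
    if (Dp >= D - 1e-12) exceed <- exceed + 1
  }
  p <- (1 + exceed) / (n_perm + 1)
  structure(list(D = D, p = p, n = c(na, nb), n_perm = n_perm),
            class = "ks2d_result")
}
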