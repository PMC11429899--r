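#' Centered moving-mean smoothing with truncated edges
#'
#' Low-pass filters a trace with a moving mean of `window` points (the
#' study setting: 10000 points = 1 s at 10 kHz), keeping only positions
#' with full support, so the output has length n - window + 1. The filter
#' is linear and shift-equivariant.
#'
#' @param trace numeric vector, or a `rhythm_trace` from
#'   [simulate_root_trace()].
#' @param window moving-mean width in samples (default 10000); must not
#'   exceed the trace length.
#' @return numeric vector of length n - window + 1.
#' @export
smooth_trace <- function(trace, window = 10000) {
  x <- if (inherits(trace, "rhythm_trace")) trace$samples else trace
  n <- length(x)
  if (window > n) stop("window (", window, ") exceeds trace length (",
                       n, ")")
  if (window == 1) return(x)
  cs <- cumsum(c(0, x))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Dominant locomotor frequency from a smoothed trace
#'
#' Mean-subtracts the trace, computes the plain (untapered) periodogram
#' power spectral density, and returns the frequency of maximum power,
#' excluding the zero-frequency bin. The spectral resolution is fs / n;
#' adding a DC offset leaves the estimate unchanged.
#'
#' @param smoothed numeric vector (typically from [smooth_trace()]).
#' @param fs sampling rate in samples/s.
#' @return frequency in Hz, with attribute `power` (the periodogram value
#'   at the peak) and `resolution` (fs/n).
#' @export
locomotor_frequency <- function(smoothed, fs) {
  x <- smoothed - mean(smoothed)
  n <- length(x)
  if (all(abs(x) < .Machine$double.eps * 10))
    stop("constant trace: frequency undefined")
  pw <- Mod(stats::fft(x))^2 / n
  half <- 2:(floor(n / 2) + 1)             # positive frequencies, no DC
  freqs <- (half - 1) * fs / n
  peak <- which.max(pw[half])
  structure(freqs[peak], power = pw[half][peak], resolution = fs / n)
}

# vertex -> arm-landmark map for the four tracked joints
joint_arm_map <- function() {
  list(wrist = c("forepaw", "elbow"),
       elbow = c("wrist", "armpit"),
       ankle = c("hindpaw", "knee"),
       knee  = c("ankle", "groin"))
}

#' Joint angle per frame from landmark coordinates
#'
#' Interior angle at the joint vertex between the two arm vectors (e.g.
#' ankle: vertex ankle, arms to hindpaw and knee), computed as the arccos
#' of the normalized dot product, in [0, 180] degrees. The angle is
#' invariant to global rotation, translation and uniform scaling of all
#' landmarks. Frames with coincident vertex/arm points give `NA` and are
#' flagged.
#'
#' @param track `landmark_track` data.frame (columns frame, landmark, x,
#'   y, confidence).
#' @param joint one of "wrist", "elbow", "ankle", "knee".
#' @return numeric vector of angles per frame (degrees); `attr(,
#'   "degenerate")` flags frames with undefined angles.
#' @export
joint_angle <- function(track, joint = c("wrist", "elbow", "ankle",
                                         "knee")) {
  joint <- match.arg(joint)
  arms <- joint_arm_map()[[joint]]
  need <- c(joint, arms)
  missing <- setdiff(need, unique(track$landmark))
  if (length(missing))
    stop("landmarks missing from track: ", paste(missing, collapse = ", "))
  get_xy <- function(lm) {
    sub <- track[track$landmark == lm, ]
    sub <- sub[order(sub$frame), ]
    cbind(sub$x, sub$y)
  }
  v0 <- get_xy(joint)
  u <- get_xy(arms[1]) - v0
  w <- get_xy(arms[2]) - v0
  nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
  degenerate <- nu < .Machine$double.eps | nw < .Machine$double.eps
  cosang <- rowSums(u * w) / (nu * nw)
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  ang[degenerate] <- NA_real_
  if (any(degenerate))
    warning(sum(degenerate), " frame(s) with coincident landmarks flagged")
  attr(ang, "degenerate") <- degenerate
  ang
}

#' Select analyzable frames
#'
#' A frame is kept iff every one of the nine landmarks has confidence at
#' least `min_confidence` and the frame does not fall in a user-supplied
#' exclusion interval (the stand-in for manual annotation of turning or
#' flipping movements).
#'
#' @param track `landmark_track` data.frame.
#' @param min_confidence minimum per-landmark confidence (default 0.9).
#' @param exclusions data.frame with `start`, `end` frame numbers
#'   (inclusive), or NULL.
#' @return logical keep-mask over frames (named by frame number).
#' @export
select_frames <- function(track, min_confidence = 0.9, exclusions = NULL) {
  frames <- sort(unique(track$frame))
  minc <- tapply(track$confidence, factor(track$frame, levels = frames),
                 min)
  keep <- as.vector(minc >= min_confidence)
  if (!is.null(exclusions) && nrow(exclusions))
    for (i in seq_len(nrow(exclusions)))
      keep <- keep & !(frames >= exclusions$start[i] &
                         frames <= exclusions$end[i])
  names(keep) <- frames
  keep
}

#' Summarize joint angles per animal and group
#'
#' Averages angles over valid frames within each animal, then reports the
#' group mean +/- SEM across animals. Animals with no valid frame are
#' excluded with a warning.
#'
#' @param angles numeric vector of per-frame angles (NA = invalid frame).
#' @param animal animal id per frame.
#' @return list: `per_animal` (named means), `mean`, `sem`.
#' @export
summarize_angles <- function(angles, animal) {
  animal <- as.character(animal)
  ok <- !is.na(angles)
  valid_animals <- unique(animal[ok])
  dropped <- setdiff(unique(animal), valid_animals)
  if (length(dropped))
    warning("animal(s) with no valid frames excluded: ",
            paste(dropped, collapse = ", "))
  per <- tapply(angles[ok], animal[ok], mean)
  m <- mean(per)
  sem <- if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else
    NA_real_
  list(per_animal = per, mean = m, sem = sem)
}
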