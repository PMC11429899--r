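test_that("moving mean matches hand computation and edge conventions", {
  expect_equal(smooth_trace(c(1, 2, 3, 4), window = 3), c(2, 3))
  expect_equal(smooth_trace(rep(5, 100), window = 10), rep(5, 91))
  x <- rnorm(50)
  expect_equal(smooth_trace(x, window = 50), mean(x))
  expect_error(smooth_trace(x, window = 51), "exceeds")
})

test_that("moving mean is linear and shift-equivariant", {
  set.seed(1)
  x <- rnorm(200); y <- rnorm(200)
  w <- 7
  expect_equal(smooth_trace(2 * x + 3 * y, w),
               2 * smooth_trace(x, w) + 3 * smooth_trace(y, w))
  shifted <- c(x[11:200])
  expect_equal(smooth_trace(shifted, w),
               smooth_trace(x, w)[11:(200 - w + 1)])
})

test_that("periodogram argmax recovers planted frequencies", {
  ## pure 0.4 Hz sinusoid, 60 s at reduced fs for speed
  tr <- simulate_root_trace(0.4, fs_hz = 200, duration_s = 60,
                            noise_sd = 0, seed = 1)
  f <- locomotor_frequency(tr$samples, tr$fs)
  expect_lt(abs(f - 0.4), 1 / 60 + 1e-9)

  ## dominant component wins: 0.3 Hz amplitude 2 + 1.0 Hz amplitude 1
  t <- seq(0, 60, by = 1 / 200)[-1]
  x <- 2 * sin(2 * pi * 0.3 * t) + sin(2 * pi * 1.0 * t)
  f2 <- locomotor_frequency(x, 200)
  expect_lt(abs(f2 - 0.3), 1 / 60 + 1e-9)

  ## DC offset invariance is exact
  expect_equal(as.numeric(locomotor_frequency(x + 100, 200)),
               as.numeric(f2))

  expect_error(locomotor_frequency(rep(3, 1000), 200), "constant")
})

test_that("frequency recovery holds across 0.1-1.0 Hz at SNR >= 1", {
  ## seeded Monte-Carlo sweep; moving-mean prefilter then periodogram
  fs <- 1000; dur <- 60
  freqs <- seq(0.1, 1.0, by = 0.1)
  for (i in seq_along(freqs)) {
    tr <- simulate_root_trace(freqs[i], fs_hz = fs, duration_s = dur,
                              burst_shape = "burst", noise_sd = 0.5,
                              seed = 100 + i)
    ## 0.2 s moving mean: below the shortest period in the sweep (a 1 s
    ## window would null the 1 Hz fundamental entirely)
    sm <- smooth_trace(tr$samples, window = fs / 5)
    f <- locomotor_frequency(sm, fs)
    expect_lt(abs(f - freqs[i]), 1 / dur + 1e-9)
  }
})

test_that("trace generator obeys length, Nyquist and determinism", {
  tr <- simulate_root_trace(0.4, fs_hz = 10000, duration_s = 60)
  expect_length(tr$samples, 600000)
  expect_error(simulate_root_trace(6000, fs_hz = 10000), "Nyquist|fs/2")
  a <- simulate_root_trace(0.5, 500, 10, noise_sd = 1, seed = 3)
  b <- simulate_root_trace(0.5, 500, 10, noise_sd = 1, seed = 3)
  expect_identical(a$samples, b$samples)
})

test_that("joint angles are exact on analytic fixtures", {
  mk_track <- function(pts) {
    data.frame(frame = 1, landmark = names(pts),
               x = vapply(pts, `[`, numeric(1), 1),
               y = vapply(pts, `[`, numeric(1), 2),
               confidence = 1)
  }
  ## collinear hindpaw-ankle-knee -> 180 degrees
  t1 <- mk_track(list(ankle = c(0, 0), hindpaw = c(-1, 0), knee = c(1, 0)))
  expect_equal(as.numeric(joint_angle(t1, "ankle")), 180)
  ## perpendicular arms -> 90
  t2 <- mk_track(list(ankle = c(0, 0), hindpaw = c(1, 0), knee = c(0, 1)))
  expect_equal(as.numeric(joint_angle(t2, "ankle")), 90)
  ## ankle (0,0), hindpaw (1,0), knee (1,1) -> 45
  t3 <- mk_track(list(ankle = c(0, 0), hindpaw = c(1, 0), knee = c(1, 1)))
  expect_equal(as.numeric(joint_angle(t3, "ankle")), 45)
  ## coincident points flagged
  t4 <- mk_track(list(ankle = c(0, 0), hindpaw = c(0, 0), knee = c(1, 1)))
  expect_warning(a4 <- joint_angle(t4, "ankle"), "coincident")
  expect_true(is.na(a4[1]))
})

test_that("joint angles are invariant under random rigid transforms", {
  set.seed(42)
  base <- data.frame(frame = 1,
                     landmark = c("ankle", "hindpaw", "knee"),
                     x = c(0, 1.3, 0.4), y = c(0, 0.2, 1.1),
                     confidence = 1)
  a0 <- as.numeric(joint_angle(base, "ankle"))
  for (r in 1:20) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10)
    dx <- rnorm(1, 0, 100); dy <- rnorm(1, 0, 100)
    tr <- base
    tr$x <- s * (cos(th) * base$x - sin(th) * base$y) + dx
    tr$y <- s * (sin(th) * base$x + cos(th) * base$y) + dy
    expect_lt(abs(as.numeric(joint_angle(tr, "ankle")) - a0), 1e-9)
  }
})

test_that("landmark simulation round-trips planted angles", {
  ## constant 90-degree knee, noise 0 -> recovered exactly every frame
  ang <- list(wrist = rep(100, 5), elbow = rep(120, 5),
              ankle = rep(70, 5), knee = rep(90, 5))
  trk <- simulate_landmarks(ang, noise_sd = 0)
  expect_equal(as.numeric(joint_angle(trk, "knee")), rep(90, 5),
               tolerance = 1e-9)
  expect_equal(as.numeric(joint_angle(trk, "ankle")), rep(70, 5),
               tolerance = 1e-9)
  expect_equal(as.numeric(joint_angle(trk, "elbow")), rep(120, 5),
               tolerance = 1e-9)
  expect_equal(as.numeric(joint_angle(trk, "wrist")), rep(100, 5),
               tolerance = 1e-9)

  ## ramp 60 -> 120 recovered within arccos numerical tolerance
  ramp <- seq(60, 120, length.out = 20)
  trk2 <- simulate_landmarks(list(wrist = rep(90, 20), elbow = rep(90, 20),
                                  ankle = rep(90, 20), knee = ramp))
  expect_equal(as.numeric(joint_angle(trk2, "knee")), ramp,
               tolerance = 1e-8)

  ## degenerate geometry rejected
  expect_error(simulate_landmarks(list(wrist = 90, elbow = 90, ankle = 90,
                                       knee = 90),
                                  segment_lengths = c(upper_arm = 0,
                                                      forearm = 1, hand = 1,
                                                      thigh = 1, shank = 1,
                                                      foot = 1)),
               "positive")
})

test_that("frame selection and angle summaries follow the stated rules", {
  lms <- c("forepaw", "wrist", "elbow", "armpit", "hindpaw", "ankle",
           "knee", "groin", "anus")
  trk <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, landmark = lms,
               x = rnorm(9), y = rnorm(9),
               confidence = if (f %in% c(2, 5, 9)) 0.5 else 1)))
  keep <- select_frames(trk, min_confidence = 0.9)
  expect_equal(sum(keep), 7)
  expect_false(any(keep[c("2", "5", "9")]))
  ## excluding frames 1-3 removes the two that had passed confidence
  keep2 <- select_frames(trk, min_confidence = 0.9,
                         exclusions = data.frame(start = 1, end = 3))
  expect_equal(sum(keep2), 5)
  expect_true(all(select_frames(trk, min_confidence = 0)))

  ## two animals at 80 and 100 degrees -> mean 90, SEM 10
  s <- summarize_angles(c(80, 80, 100, 100), c("m1", "m1", "m2", "m2"))
  expect_equal(s$mean, 90)
  expect_equal(s$sem, 10)
  ## permuting frames leaves summaries unchanged
  s2 <- summarize_angles(c(100, 80, 100, 80), c("m2", "m1", "m2", "m1"))
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$sem, s$sem)
  expect_warning(summarize_angles(c(NA, 90), c("m1", "m2")), "excluded")
})
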