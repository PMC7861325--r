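test_that("eye magnitude averages the two eyes' coordinate magnitudes", {
  g <- make_gaze(xL = c(3, 0, 0), yL = c(4, 0, 0),
                 xR = c(3, 0, 6), yR = c(4, 0, 8))
  expect_equal(eye_magnitude(g), c(5, 0, 5))  # 3-4-5 triangles

  # invariant to swapping the eyes
  swapped <- make_gaze(xL = g$xR, yL = g$yR, xR = g$xL, yR = g$yL)
  expect_equal(eye_magnitude(swapped), eye_magnitude(g))

  # homogeneous of degree 1 in the coordinates
  scaled <- make_gaze(xL = 2.5 * g$xL, yL = 2.5 * g$yL,
                      xR = 2.5 * g$xR, yR = 2.5 * g$yR)
  expect_equal(eye_magnitude(scaled), 2.5 * eye_magnitude(g))

  bad <- make_gaze(c(1, 2)); bad$yR <- 1
  expect_error(eye_magnitude(bad), "length")
})

test_that("blink detection applies the strict >20 ms run rule", {
  p <- blink_params(magnitude_threshold = 0.5)
  mk <- function(lens_low, lens_high = lens_low * 0 + 50) {
    # alternate above/below threshold runs, starting above
    unlist(mapply(function(lo, hi) c(rep(1, hi), rep(0, lo)),
                  lens_low, lens_high, SIMPLIFY = FALSE))
  }
  # 30 ms sub-threshold run at 1000 Hz -> one 30 ms event
  ev <- detect_blinks(mk(30), 1000, p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 30)
  # 10 ms and exactly-20 ms runs are not blinks
  expect_equal(nrow(detect_blinks(mk(10), 1000, p)), 0)
  expect_equal(nrow(detect_blinks(mk(20), 1000, p)), 0)
  # two runs of 25 and 40 ms: durations {25, 40}, mean 32.5
  ev2 <- detect_blinks(mk(c(25, 40)), 1000, p)
  expect_equal(ev2$duration_ms, c(25, 40))
  expect_equal(mean(ev2$duration_ms), 32.5)
  # a run touching the end of the recording is closed at the last sample
  tail_run <- c(rep(1, 10), rep(0, 30))
  ev3 <- detect_blinks(tail_run, 1000, p)
  expect_equal(ev3$end, 0.04)
  expect_equal(nrow(detect_blinks(numeric(0), 1000, p)), 0)
})

test_that("blink detection matches a brute-force per-sample oracle", {
  set.seed(99)
  for (i in 1:60) {
    mag <- ifelse(runif(200) < 0.3, runif(200, 0, 0.4), runif(200, 0.6, 2))
    p <- blink_params(magnitude_threshold = 0.5,
                      min_blink_ms = sample(c(5, 20, 35), 1))
    got <- detect_blinks(mag, 1000, p)
    want <- brute_blinks(mag, 1000, 0.5, p$min_blink_ms)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("blink and fixation indices normalize by session minutes", {
  ev <- data.frame(start = seq_len(30), end = seq_len(30) + 0.1,
                   duration_ms = rep(c(100, 300), 15))
  bi <- blink_indices(ev, 10)
  expect_equal(bi$blink_freq, 3)
  expect_equal(bi$blink_duration_mean, 200)
  none <- blink_indices(ev[0, ], 10)
  expect_equal(none$blink_freq, 0)
  expect_true(is.na(none$blink_duration_mean))
  fi <- fixation_indices(ev, 10)
  expect_equal(fi$fixation_freq, 3)
  expect_equal(fi$fixation_duration_mean, 200)
  expect_error(blink_indices(ev, 0), "session_minutes")
})

test_that("I-DT fixation detection handles the canonical extremes", {
  rate <- 50
  # perfectly constant gaze for 600 s -> one 600 s fixation
  n <- 600 * rate
  g <- make_gaze(rep(0.5, n), rate = rate)
  fx <- detect_fixations(g, fixation_params(dispersion_threshold = 0.01),
                         exclude_blinks = FALSE)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 600 * 1000)
  # far-apart alternating points every sample -> no fixations
  alt <- make_gaze(rep(c(0.1, 0.9), 100), rate = rate)
  fx2 <- detect_fixations(alt, fixation_params(dispersion_threshold = 0.01),
                          exclude_blinks = FALSE)
  expect_equal(nrow(fx2), 0)
})

test_that("I-DT recovers exactly the planted fixations", {
  rate <- 50
  n_fix <- 90
  len <- 15  # 300 ms each
  centers <- rep(c(0.3, 0.6), length.out = n_fix)
  x <- rep(centers, each = len)
  g <- make_gaze(x, rate = rate)
  fx <- detect_fixations(g, fixation_params(dispersion_threshold = 0.05,
                                            min_fixation_ms = 100),
                         exclude_blinks = FALSE)
  expect_equal(nrow(fx), n_fix)
  expect_equal(fx$duration_ms, rep(300, n_fix))
})

test_that("fixations never overlap blink-excluded regions", {
  cfg <- study_config(session_duration = 120, seed = 8)
  g <- generate_gaze(subject_profile(), drive = 2, cfg, seed = 8)
  bl <- detect_blinks(eye_magnitude(g), g$rate)
  fx <- detect_fixations(g)
  expect_gt(nrow(bl), 0)
  expect_gt(nrow(fx), 0)
  # events sorted and pairwise non-overlapping
  for (ev in list(bl, fx)) {
    expect_true(all(diff(ev$start) > 0))
    expect_true(all(ev$end[-nrow(ev)] <= ev$start[-1] + 1e-9))
  }
  # no fixation interval intersects a blink interval
  for (i in seq_len(nrow(bl))) {
    expect_false(any(fx$start < bl$end[i] - 1e-9 &
                     fx$end > bl$start[i] + 1e-9))
  }
})

test_that("coordinate rescaling with rescaled thresholds preserves events", {
  cfg <- study_config(session_duration = 60, seed = 12)
  g <- generate_gaze(subject_profile(), drive = 1, cfg, seed = 12)
  c_ <- 7.3
  gs <- make_gaze(c_ * g$xL, c_ * g$yL, c_ * g$xR, c_ * g$yR, rate = g$rate)
  expect_equal(eye_magnitude(gs), c_ * eye_magnitude(g))
  thr <- 0.05 * median(eye_magnitude(g))
  b1 <- detect_blinks(eye_magnitude(g), g$rate,
                      blink_params(magnitude_threshold = thr))
  b2 <- detect_blinks(eye_magnitude(gs), g$rate,
                      blink_params(magnitude_threshold = c_ * thr))
  expect_equal(nrow(b1), nrow(b2))
  f1 <- detect_fixations(g, fixation_params(dispersion_threshold = 0.01),
                         blink_params(magnitude_threshold = thr))
  f2 <- detect_fixations(gs, fixation_params(dispersion_threshold = c_ * 0.01),
                         blink_params(magnitude_threshold = c_ * thr))
  expect_equal(nrow(f1), nrow(f2))
})

test_that("facial-channel indices are per-channel means", {
  n <- 50
  ch <- matrix(0.3, n, 21, dimnames = list(NULL, ft_channels()))
  ch[, "smile"] <- rep(c(0, 1), n / 2)
  out <- ft_indices(ch)
  expect_equal(unname(out["brow_furrow"]), 0.3)
  expect_equal(unname(out["smile"]), 0.5)
  expect_length(out, 21)

  # two-pass mean agrees with a streaming (one-pass) oracle to 1e-12
  set.seed(4)
  ch[, "pitch"] <- runif(n)
  stream <- 0
  for (i in seq_len(n)) stream <- stream + (ch[i, "pitch"] - stream) / i
  expect_equal(unname(ft_indices(ch)["pitch"]), unname(stream),
               tolerance = 1e-12)

  expect_error(ft_indices(ch[, 1:5]), "21 named channels")
  expect_error(ft_indices(ch[0, , drop = FALSE]), "non-empty")

  # min-max rescaling maps channels onto [0, 1]
  ch[, "yaw"] <- ch[, "yaw"] * 90 - 45
  r <- ft_indices(ch, rescale = TRUE)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("feature extraction yields the 25 named indices per session", {
  st <- generate_study(study_config(n_subjects = 2, n_sessions = 3,
                                    session_duration = 30,
                                    missing_fraction = 0, seed = 21))
  f <- extract_features(st)
  expect_equal(nrow(f), 6)
  expect_true(all(feature_names() %in% names(f)))
  expect_false(anyNA(f[, c("blink_frequency", "fixation_frequency",
                           ft_channels())]))
})

test_that("missing event-duration features are imputed as zero with warning", {
  d <- data.frame(blink_duration = c(NA, 120), blink_frequency = c(0, 3))
  expect_warning(out <- impute_missing_features(d), "imputing")
  expect_equal(out$blink_duration, c(0, 120))
})
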