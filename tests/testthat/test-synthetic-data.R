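test_that("study generation is deterministic and respects the design shape", {
  cfg <- study_config(n_subjects = 3, n_sessions = 4, session_duration = 30,
                      missing_fraction = 0, seed = 11)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)

  # default design: 20 x 13 = 260 session slots, none missing at fraction 0
  full <- generate_study(study_config(missing_fraction = 0, seed = 3),
                         signals = "pvt")
  expect_equal(nrow(full$index), 260)
  expect_equal(sum(full$index$missing), 0)
  expect_true(all(full$index$excluded == (full$index$session == 1)))

  # subject substreams: adding a subject leaves earlier subjects untouched
  a <- generate_study(study_config(n_subjects = 2, n_sessions = 3,
                                   session_duration = 30, seed = 7))
  b <- generate_study(study_config(n_subjects = 3, n_sessions = 3,
                                   session_duration = 30, seed = 7))
  expect_identical(a$sessions[1:6], b$sessions[1:6])
  expect_identical(a$profiles, b$profiles[1:2])
})

test_that("config invariants are enforced", {
  expect_error(study_config(n_subjects = 1), "n_subjects")
  expect_error(study_config(isi_range = c(5, 5)), "isi_range")
  expect_error(study_config(missing_fraction = 1), "missing_fraction")
  expect_error(subject_profile(blink_dur_base = -1), "rates")
  sh <- setNames(rep(0.5, 21), ft_channels())
  expect_error(subject_profile(ft_channel_means = sh + 0.4,
                               ft_impairment_shift = sh), "\\[0, 1\\]")
})

test_that("PVT session logs respect stimulus timing and the lapse mixture", {
  cfg <- study_config(seed = 1)
  prof <- subject_profile()
  log <- generate_pvt_session(prof, drive = 0, cfg, seed = 42)
  n <- length(log$stimulus_times)
  # ISI bounds: 600 s / [2, 10] s intervals plus response times
  expect_gte(n, 50)
  expect_lte(n, 300)
  expect_true(all(diff(log$stimulus_times) > 0))
  gaps <- diff(log$stimulus_times) - log$rts[-n] / 1000
  expect_true(all(gaps >= cfg$isi_range[1] - 1e-9))
  expect_true(all(gaps <= cfg$isi_range[2] + 1e-9))

  # zero-length session
  empty <- generate_pvt_session(prof, 0, study_config(session_duration = 0),
                                seed = 1)
  expect_length(empty$rts, 0)

  # lapse weight forced to 1 with the tail above 1000 ms: every response is
  # both a lapse and a major lapse
  forced <- generate_pvt_session(
    subject_profile(lapse_rate_base = 1, lapse_tail_location = 1000),
    drive = 0, cfg, seed = 5)
  sc <- score_session(forced)
  expect_equal(sc$n_lapses, length(forced$rts))
  expect_equal(sc$n_major, length(forced$rts))
})

test_that("impairment drive raises the expected PVT score (paired seeds)", {
  cfg <- study_config(seed = 1)
  prof <- subject_profile()
  scores <- vapply(c(low = 0, high = 1), function(drv) {
    mean(vapply(1:200, function(s) {
      score_session(generate_pvt_session(prof, drv, cfg, seed = s))$score
    }, numeric(1)))
  }, numeric(1))
  expect_gt(scores["high"], scores["low"])
})

test_that("gaze generator plants recoverable blinks", {
  cfg <- study_config(session_duration = 120, seed = 2)
  # no blinks at zero frequency
  quiet <- generate_gaze(subject_profile(blink_freq_base = 0,
                                         blink_freq_slope = 0,
                                         blink_freq_session_sd = 0),
                         drive = 0, cfg, seed = 3)
  expect_equal(nrow(quiet$ledger$blinks), 0)
  expect_equal(nrow(detect_blinks(eye_magnitude(quiet), quiet$rate)), 0)

  # detector output matches the generator's event ledger exactly
  g <- generate_gaze(subject_profile(), drive = 1, cfg, seed = 4)
  det <- detect_blinks(eye_magnitude(g), g$rate)
  led <- g$ledger$blinks
  expect_equal(nrow(det), nrow(led))
  expect_equal(det$start, led$start)
  expect_equal(det$duration_ms, led$duration * 1000)

  # mean duration of planted events is recovered within one sample period
  expect_lt(abs(mean(det$duration_ms) - mean(led$duration) * 1000),
            1000 / g$rate + 1e-9)

  # impairment lengthens blinks (session wander silenced, same seed)
  p0 <- subject_profile(blink_dur_session_sd = 0, blink_freq_session_sd = 0,
                        fix_dur_session_sd = 0)
  g0 <- generate_gaze(p0, drive = 0, cfg, seed = 9)
  g3 <- generate_gaze(p0, drive = 3, cfg, seed = 9)
  expect_gt(mean(g3$ledger$blinks$duration), mean(g0$ledger$blinks$duration))
})

test_that("facial channels track their configured means, shifts and range", {
  cfg <- study_config(session_duration = 60, seed = 1)
  exact <- subject_profile(ft_noise_sd = 0, ft_session_sd = 0,
                           ft_impairment_shift = setNames(rep(0, 21),
                                                          ft_channels()))
  f <- generate_ft_series(exact, drive = 2, cfg, seed = 1)
  expect_equal(colMeans(f$channels), exact$ft_channel_means)

  # noisy channels stay clipped to [0, 1]
  noisy <- generate_ft_series(subject_profile(ft_noise_sd = 0.5), 1, cfg,
                              seed = 2)
  expect_gte(min(noisy$channels), 0)
  expect_lte(max(noisy$channels), 1)

  # the positive eye-closure shift raises the impaired-class mean
  p <- subject_profile(ft_noise_sd = 0.02, ft_session_sd = 0)
  m0 <- mean(generate_ft_series(p, 0, cfg, seed = 3)$channels[, "eye_closure"])
  m3 <- mean(generate_ft_series(p, 3, cfg, seed = 3)$channels[, "eye_closure"])
  expect_gt(m3, m0)
})

test_that("a slope-free population yields no detectable session effect", {
  # with lapse_rate_slope = 0 every session has the same score distribution,
  # so the downstream ANOVA should reject at about its nominal 5% rate; the
  # binomial 99% bound on 100 draws at that rate allows at most 10 rejections
  profiles <- lapply(1:20, function(i) flat_profile())
  p_over_alpha <- vapply(1:100, function(s) {
    st <- generate_study(study_config(seed = 20000 + s), signals = "pvt",
                         profiles = profiles)
    anova_sessions(score_study(st))$p > 0.05
  }, logical(1))
  expect_lte(sum(!p_over_alpha), 10)
})

test_that("studies round-trip through the plain-text interchange files", {
  dir <- withr::local_tempdir()
  st <- generate_study(study_config(n_subjects = 2, n_sessions = 2,
                                    session_duration = 10,
                                    missing_fraction = 0, seed = 5))
  write_study(st, dir)
  g <- read_gaze_csv(file.path(dir, "subject_01", "session_01_gaze.csv"))
  orig <- st$sessions[[1]]$gaze
  expect_equal(g$xL, orig$xL, tolerance = 1e-6)
  expect_equal(g$rate, orig$rate, tolerance = 1e-6)
  f <- read_ft_csv(file.path(dir, "subject_01", "session_01_ft.csv"))
  expect_equal(ft_indices(f), ft_indices(st$sessions[[1]]$ft),
               tolerance = 1e-6)
  pv <- read_pvt_csv(file.path(dir, "subject_01", "session_01_pvt.csv"),
                     duration = 10)
  expect_equal(sort(pv$rts), sort(st$sessions[[1]]$pvt$rts),
               tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
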