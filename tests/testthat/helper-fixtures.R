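# Shared fixtures and independent oracles, built in code.

# Minimal gaze recording from coordinate vectors.
make_gaze <- function(xL, yL = xL, xR = xL, yR = yL, rate = 1000) {
  structure(list(t = (seq_along(xL) - 1) / rate, xL = xL, yL = yL,
                 xR = xR, yR = yR, rate = rate, ledger = NULL),
            class = "gaze_recording")
}

# Brute-force blink oracle: per-sample scan for maximal sub-threshold runs,
# independent of the rle-based detector.
brute_blinks <- function(mag, rate, thr, min_ms = 20, max_ms = Inf) {
  out <- list()
  n <- length(mag)
  i <- 1
  while (i <= n) {
    if (mag[i] < thr) {
      j <- i
      while (j < n && mag[j + 1] < thr) j <- j + 1
      dur <- (j - i + 1) / rate * 1000
      if (dur > min_ms && dur <= max_ms) {
        out[[length(out) + 1]] <- data.frame(
          start = (i - 1) / rate, end = j / rate, duration_ms = dur)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = numeric(0), end = numeric(0),
               duration_ms = numeric(0))
}

# Labeled feature data with a planted class shift on a few columns; uses a
# subset of the canonical feature names so wrapper searches stay small.
make_toy_labeled <- function(n_subjects = 8, rows_per = 12,
                             n_features = 12, informative = 1:4,
                             shift = 2, seed = 1, frac_impaired = 0.4) {
  set.seed(seed)
  n <- n_subjects * rows_per
  fn <- feature_names()[seq_len(n_features)]
  X <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, fn))
  label <- factor(ifelse(runif(n) < frac_impaired, "impaired", "normal"),
                  levels = c("normal", "impaired"))
  X[label == "impaired", informative] <-
    X[label == "impaired", informative] + shift
  data.frame(subject = rep(seq_len(n_subjects), each = rows_per),
             session = rep(seq_len(rows_per), n_subjects),
             label = label, X, check.names = FALSE)
}

# A quiet subject profile: no impairment response anywhere.
flat_profile <- function(...) {
  subject_profile(lapse_rate_slope = 0, blink_dur_slope = 0,
                  blink_freq_slope = 0, fix_dur_slope = 0,
                  ft_impairment_shift = setNames(rep(0, 21), ft_channels()),
                  ...)
}
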