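#' Ensemble-averaged eye-coordinate magnitude signal
#'
#' Per-sample mean of the two eyes' Euclidean coordinate magnitudes,
#' `( sqrt(xL^2 + yL^2) + sqrt(xR^2 + yR^2) ) / 2`. The magnitude serves as
#' a general eye-activity signal: it collapses toward zero when the tracker
#' loses the eyes (blinks), which is what the blink detector exploits.
#'
#' @param gaze A `gaze_recording` (see [generate_gaze()], [read_gaze_csv()]).
#' @return Numeric vector, one magnitude per sample.
#' @examples
#' g <- structure(list(t = 0, xL = 3, yL = 4, xR = 3, yR = 4, rate = 50),
#'                class = "gaze_recording")
#' eye_magnitude(g)  # 5
#' @export
eye_magnitude <- function(gaze) {
  n <- length(gaze$t)
  if (length(gaze$xL) != n || length(gaze$yL) != n ||
      length(gaze$xR) != n || length(gaze$yR) != n)
    stop("gaze coordinate vectors must all match the length of t",
         call. = FALSE)
  (sqrt(gaze$xL^2 + gaze$yL^2) + sqrt(gaze$xR^2 + gaze$yR^2)) / 2
}

#' Blink-detection parameters
#'
#' @param magnitude_threshold Magnitude cutoff below which the signal counts
#'   as lost. `NULL` (default) uses 5% of the session's median magnitude —
#'   a reproducible stand-in for a visually chosen near-zero threshold.
#' @param min_blink_ms Minimum duration (ms); runs must be strictly longer
#'   than this to count as blinks (default 20, so a run of exactly 20 ms is
#'   not a blink).
#' @param max_blink_ms Maximum duration (ms); `Inf` leaves blinks unbounded.
#' @return An object of class `blink_params`.
#' @export
blink_params <- function(magnitude_threshold = NULL, min_blink_ms = 20,
                         max_blink_ms = Inf) {
  if (!is.null(magnitude_threshold) && magnitude_threshold < 0)
    stop("magnitude_threshold must be >= 0", call. = FALSE)
  if (min_blink_ms <= 0) stop("min_blink_ms must be > 0", call. = FALSE)
  structure(list(magnitude_threshold = magnitude_threshold,
                 min_blink_ms = min_blink_ms, max_blink_ms = max_blink_ms),
            class = "blink_params")
}

resolve_blink_threshold <- function(magnitude, params) {
  params$magnitude_threshold %||% (0.05 * median(magnitude))
}

#' Detect blink events in a magnitude signal
#'
#' Maximal runs of consecutive samples whose magnitude falls below the
#' threshold become blink events when their duration strictly exceeds
#' `min_blink_ms`. A blink ends at the first sample back above threshold;
#' a run touching the end of the recording is closed at the last sample.
#'
#' @param magnitude Numeric magnitude signal (see [eye_magnitude()]).
#' @param rate Sampling rate in Hz.
#' @param params A [blink_params()].
#' @return A data frame of events with columns `start`, `end` (seconds) and
#'   `duration_ms`, sorted and non-overlapping.
#' @export
detect_blinks <- function(magnitude, rate, params = blink_params()) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (length(magnitude) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration_ms = numeric(0)))
  thr <- resolve_blink_threshold(magnitude, params)
  r <- rle(magnitude < thr)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  starts_idx <- starts_idx[keep]; lens <- r$lengths[keep]
  dur_ms <- lens / rate * 1000
  ok <- dur_ms > params$min_blink_ms & dur_ms <= params$max_blink_ms
  data.frame(start = (starts_idx[ok] - 1L) / rate,
             end = (starts_idx[ok] - 1L + lens[ok]) / rate,
             duration_ms = dur_ms[ok])
}

#' Blink indices for one session
#'
#' @param events Blink-event data frame from [detect_blinks()].
#' @param session_minutes Session length in minutes (frequency denominator).
#' @return List with `blink_duration_mean` (ms; `NA` when no events — a
#'   flagged-missing value, imputed downstream) and `blink_freq` (events
#'   per minute).
#' @export
blink_indices <- function(events, session_minutes) {
  if (session_minutes <= 0) stop("session_minutes must be > 0", call. = FALSE)
  list(blink_duration_mean = if (nrow(events)) mean(events$duration_ms)
       else NA_real_,
       blink_freq = nrow(events) / session_minutes)
}

#' Fixation-detection parameters (I-DT)
#'
#' @param dispersion_threshold Maximum window dispersion, measured as
#'   (max-min of x) + (max-min of y) of the averaged-eye position, in
#'   coordinate units. `NULL` (default) uses 1% of the session's coordinate
#'   range.
#' @param min_fixation_ms Minimum fixation duration in ms (default 100).
#' @return An object of class `fixation_params`.
#' @export
fixation_params <- function(dispersion_threshold = NULL,
                            min_fixation_ms = 100) {
  if (!is.null(dispersion_threshold) && dispersion_threshold <= 0)
    stop("dispersion_threshold must be > 0", call. = FALSE)
  if (min_fixation_ms <= 0) stop("min_fixation_ms must be > 0", call. = FALSE)
  structure(list(dispersion_threshold = dispersion_threshold,
                 min_fixation_ms = min_fixation_ms),
            class = "fixation_params")
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Blink samples (from [detect_blinks()]) are excluded first and the signal
#' is split at the resulting gaps, so no fixation spans a blink. Within each
#' contiguous segment a window over the averaged-eye position grows while
#' its dispersion — (max-min of x) + (max-min of y) — stays within the
#' threshold; windows covering at least `min_fixation_ms` become fixations.
#'
#' @param gaze A `gaze_recording`.
#' @param params A [fixation_params()].
#' @param bparams A [blink_params()] used for the blink exclusion.
#' @param exclude_blinks Set `FALSE` to skip the blink exclusion.
#' @return Data frame of events with `start`, `end` (seconds) and
#'   `duration_ms`, sorted and non-overlapping.
#' @export
detect_fixations <- function(gaze, params = fixation_params(),
                             bparams = blink_params(),
                             exclude_blinks = TRUE) {
  n <- length(gaze$t)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration_ms = numeric(0))
  if (n == 0) return(empty)
  rate <- gaze$rate
  keep <- rep(TRUE, n)
  if (exclude_blinks) {
    mag <- eye_magnitude(gaze)
    # drop every sub-threshold sample: blinks, and shorter dropouts that
    # are signal loss rather than gaze positions
    thr <- resolve_blink_threshold(mag, bparams)
    keep <- mag >= thr
  }
  if (!any(keep)) return(empty)
  x <- (gaze$xL + gaze$xR)[keep] / 2
  y <- (gaze$yL + gaze$yR)[keep] / 2
  tt <- gaze$t[keep]
  disp <- params$dispersion_threshold %||%
    (0.01 * ((max(x) - min(x)) + (max(y) - min(y))))
  if (disp <= 0) disp <- .Machine$double.eps
  min_samples <- max(1L, as.integer(ceiling(params$min_fixation_ms / 1000 * rate)))
  # split at gaps left by excluded samples
  seg <- cumsum(c(TRUE, diff(tt) > 1.5 / rate))
  out <- lapply(split(seq_along(tt), seg), function(ix) {
    runs <- idt_runs_cpp(x[ix], y[ix], disp, min_samples)
    if (nrow(runs) == 0) return(NULL)
    data.frame(start = tt[ix[runs[, 1]]],
               end = tt[ix[runs[, 2]]] + 1 / rate,
               duration_ms = (runs[, 2] - runs[, 1] + 1) / rate * 1000)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out[order(out$start), ]
  }
}

#' Fixation indices for one session
#'
#' @param events Fixation-event data frame from [detect_fixations()].
#' @param session_minutes Session length in minutes.
#' @return List with `fixation_duration_mean` (ms; `NA` when no events) and
#'   `fixation_freq` (per minute).
#' @export
fixation_indices <- function(events, session_minutes) {
  if (session_minutes <= 0) stop("session_minutes must be > 0", call. = FALSE)
  list(fixation_duration_mean = if (nrow(events)) mean(events$duration_ms)
       else NA_real_,
       fixation_freq = nrow(events) / session_minutes)
}

#' Facial-channel indices: per-channel mean probability
#'
#' @param ft An `ft_series` or a samples-by-21 matrix/data frame with the
#'   channel names of [ft_channels()].
#' @param rescale Set `TRUE` to min-max rescale each channel to \[0, 1\]
#'   first (for real exports whose head-pose channels are in degrees).
#' @return Named numeric vector of 21 channel means.
#' @export
ft_indices <- function(ft, rescale = FALSE) {
  ch <- if (inherits(ft, "ft_series")) ft$channels else as.matrix(ft)
  if (is.null(colnames(ch)) || !all(ft_channels() %in% colnames(ch)))
    stop("ft must carry the 21 named channels", call. = FALSE)
  ch <- ch[, ft_channels(), drop = FALSE]
  if (nrow(ch) == 0) stop("each channel must be non-empty", call. = FALSE)
  if (rescale) {
    ch <- apply(ch, 2, function(v) {
      r <- max(v) - min(v)
      if (r == 0) v * 0 else (v - min(v)) / r
    })
    if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1,
                                       dimnames = list(NULL, ft_channels()))
  }
  colMeans(ch)
}

#' All 25 predictive indices for one session
#'
#' Combines the four eye-tracking indices (blink duration/frequency,
#' fixation duration/frequency) with the 21 facial-channel means into one
#' named feature vector; see [feature_names()] for the order.
#'
#' @param gaze A `gaze_recording`.
#' @param ft An `ft_series`.
#' @param bparams,fparams Detection parameters.
#' @return Named numeric vector of length 25. Blink/fixation mean durations
#'   are `NA` when no events occurred (imputed before model training by
#'   [impute_missing_features()]).
#' @export
session_features <- function(gaze, ft, bparams = blink_params(),
                             fparams = fixation_params()) {
  minutes <- length(gaze$t) / gaze$rate / 60
  mag <- eye_magnitude(gaze)
  bl <- detect_blinks(mag, gaze$rate, bparams)
  fx <- detect_fixations(gaze, fparams, bparams)
  bi <- blink_indices(bl, minutes)
  fi <- fixation_indices(fx, minutes)
  c(blink_duration = bi$blink_duration_mean,
    blink_frequency = bi$blink_freq,
    fixation_duration = fi$fixation_duration_mean,
    fixation_frequency = fi$fixation_freq,
    ft_indices(ft))
}

#' Extract the per-session feature table of a study
#'
#' @param study A [generate_study()] result containing gaze and ft signals.
#' @param bparams,fparams Detection parameters.
#' @return Data frame with `subject`, `session`, `hours_awake` and the 25
#'   feature columns; one row per non-missing session.
#' @export
extract_features <- function(study, bparams = blink_params(),
                             fparams = fixation_params()) {
  rows <- which(!study$index$missing)
  feats <- lapply(rows, function(i) {
    rec <- study$sessions[[i]]
    if (is.null(rec$gaze) || is.null(rec$ft))
      stop("study lacks gaze/ft signals; regenerate with signals = c('gaze','ft',...)",
           call. = FALSE)
    session_features(rec$gaze, rec$ft, bparams, fparams)
  })
  out <- cbind(study$index[rows, c("subject", "session", "hours_awake")],
               do.call(rbind, feats))
  rownames(out) <- NULL
  out
}

#' Impute flagged-missing event-duration features
#'
#' Sessions without any detected blink or fixation carry `NA` mean
#' durations; before model training these are imputed as 0 with a warning.
#'
#' @param data Data frame containing feature columns.
#' @return The data frame with `NA` feature values replaced by 0.
#' @export
impute_missing_features <- function(data) {
  fcols <- intersect(feature_names(), names(data))
  nas <- vapply(data[fcols], anyNA, logical(1))
  if (any(nas)) {
    warning("imputing ", sum(vapply(data[fcols], function(x) sum(is.na(x)),
                                    numeric(1))),
            " missing feature value(s) as 0 in: ",
            paste(fcols[nas], collapse = ", "), call. = FALSE)
    for (cc in fcols[nas]) data[[cc]][is.na(data[[cc]])] <- 0
  }
  data
}
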