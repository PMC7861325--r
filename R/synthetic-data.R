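#' Impairment drive as a function of hours awake
#'
#' Ground-truth impairment for the synthetic study: zero until the subject's
#' onset, then increasing by one unit per session thereafter, so the session
#' at `onset_hours` is the first with non-zero drive. The drive multiplies
#' the profile's lapse, blink and facial-channel slopes.
#'
#' @param hours Hours awake (vector allowed).
#' @param onset_hours Hours awake at impairment onset.
#' @param spacing_h Session spacing in hours (drive unit).
#' @return Non-negative numeric, non-decreasing in `hours`.
#' @export
impairment_drive <- function(hours, onset_hours = 17, spacing_h = 2) {
  ifelse(hours >= onset_hours, (hours - onset_hours) / spacing_h + 1, 0)
}

#' Simulate one PVT session's event log
#'
#' Stimuli appear at inter-stimulus intervals drawn uniformly from
#' `config$isi_range`, each interval starting when the previous response
#' ends. Reaction times follow a lognormal body centred on the subject's
#' alert median, mixed with a lapse tail: with probability
#' `min(1, lapse_rate_base + lapse_rate_slope * drive)` the RT is drawn
#' above `lapse_tail_location` ms (a lognormal excess, so a fraction of
#' lapses exceed 1000 ms and count as major lapses). False starts are a
#' Poisson count placed uniformly in session time.
#'
#' @param profile A [subject_profile()].
#' @param drive Non-negative impairment drive (see [impairment_drive()]).
#' @param config A [study_config()].
#' @param seed Optional integer seed for this session's draws.
#' @return An object of class `pvt_log`: list with `stimulus_times` (s),
#'   `rts` (ms, one per stimulus), `false_start_times` (s),
#'   `duration` (s) and the ground-truth `lapse_draws` logical ledger.
#' @examples
#' log <- generate_pvt_session(subject_profile(), drive = 0,
#'                             config = study_config(), seed = 1)
#' length(log$rts)
#' @export
generate_pvt_session <- function(profile, drive, config, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), drive >= 0)
  dur <- config$session_duration
  empty <- function() structure(
    list(stimulus_times = numeric(0), rts = numeric(0),
         false_start_times = numeric(0), duration = dur,
         lapse_draws = logical(0)),
    class = "pvt_log")
  if (dur <= 0) return(empty())
  with_seed(seed, {
    n_max <- ceiling(dur / config$isi_range[1]) + 1L
    isi <- runif(n_max, config$isi_range[1], config$isi_range[2])
    p_lapse <- min(1, profile$lapse_rate_base +
                     profile$lapse_rate_slope * drive)
    is_lapse <- runif(n_max) < p_lapse
    sdlog <- profile$baseline_rt_sd / profile$baseline_rt_mean
    body <- rlnorm(n_max, log(profile$baseline_rt_mean), sdlog)
    tail <- profile$lapse_tail_location + rlnorm(n_max, log(250), 0.9)
    rt <- ifelse(is_lapse, tail, body)
    # stimulus k appears isi[k] seconds after response k-1
    t_stim <- cumsum(isi + c(0, rt[-n_max] / 1000))
    keep <- t_stim <= dur
    n_fs <- rpois(1, profile$false_start_rate)
    structure(list(
      stimulus_times = t_stim[keep],
      rts = rt[keep],
      false_start_times = sort(runif(n_fs, 0, dur)),
      duration = dur,
      lapse_draws = is_lapse[keep]
    ), class = "pvt_log")
  })
}

#' @export
print.pvt_log <- function(x, ...) {
  cat("PVT event log:", length(x$rts), "stimuli,",
      length(x$false_start_times), "false starts over", x$duration, "s\n")
  invisible(x)
}

#' Simulate one session's binocular gaze recording
#'
#' Gaze follows a fixation-saccade process: piecewise-constant fixation
#' centres (uniform over the central field) with small Gaussian jitter, and
#' instantaneous saccades between centres. Blinks are inserted as runs where
#' both eyes' coordinates drop to (0, 0) — the signal-loss encoding used by
#' glasses-type eye trackers — with mean duration
#' `blink_dur_base + blink_dur_slope * drive` and rate
#' `blink_freq_base + blink_freq_slope * drive` per minute. The generator
#' keeps a private ledger of the true blink and fixation events for use as a
#' detector oracle.
#'
#' @inheritParams generate_pvt_session
#' @return An object of class `gaze_recording`: list with `t` (s),
#'   `xL`, `yL`, `xR`, `yR`, `rate` (Hz) and a `ledger` of true events.
#' @export
generate_gaze <- function(profile, drive, config, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), drive >= 0)
  rate <- config$gaze_rate
  dur <- config$session_duration
  n <- round(dur * rate)
  if (n <= 0) {
    return(structure(list(t = numeric(0), xL = numeric(0), yL = numeric(0),
                          xR = numeric(0), yR = numeric(0), rate = rate,
                          ledger = list(blinks = data.frame(), fixations = data.frame())),
                     class = "gaze_recording"))
  }
  with_seed(seed, {
    tt <- (seq_len(n) - 1) / rate
    # --- fixation sequence ---
    fix_mean <- max(150, profile$fix_dur_base +
                      profile$fix_dur_slope * drive +
                      rnorm(1, 0, profile$fix_dur_session_sd))  # ms
    n_fix_max <- ceiling(dur * 1000 / 120) + 2L
    durs <- pmax(120, rgamma(n_fix_max, shape = 6, scale = fix_mean / 6))
    n_samp_fix <- pmax(6L, as.integer(round(durs / 1000 * rate)))
    cum <- cumsum(n_samp_fix)
    k <- which(cum >= n)[1]
    n_samp_fix <- n_samp_fix[seq_len(k)]
    n_samp_fix[k] <- n_samp_fix[k] - (cum[k] - n)
    fix_id <- rep.int(seq_len(k), n_samp_fix)
    cx <- runif(k, 0.25, 0.95)
    cy <- runif(k, 0.25, 0.95)
    j <- profile$gaze_jitter
    xL <- cx[fix_id] + rnorm(n, 0, j); yL <- cy[fix_id] + rnorm(n, 0, j)
    xR <- cx[fix_id] + rnorm(n, 0, j); yR <- cy[fix_id] + rnorm(n, 0, j)
    fix_start <- c(0, cumsum(n_samp_fix))[seq_len(k)] / rate
    fixations <- data.frame(start = fix_start,
                            end = fix_start + n_samp_fix / rate,
                            duration = n_samp_fix / rate)
    # --- blink insertion (non-overlapping runs of (0,0)) ---
    freq <- max(0, profile$blink_freq_base +
                  profile$blink_freq_slope * drive +
                  rnorm(1, 0, profile$blink_freq_session_sd))
    if (profile$blink_freq_base + profile$blink_freq_slope * drive == 0)
      freq <- 0  # a non-blinking profile stays non-blinking
    n_blink <- rpois(1, freq * dur / 60)
    blinks <- data.frame(start = numeric(0), end = numeric(0),
                         duration = numeric(0))
    if (n_blink > 0) {
      bdur_mean <- max(60, profile$blink_dur_base +
                         profile$blink_dur_slope * drive +
                         rnorm(1, 0, profile$blink_dur_session_sd))
      bdur_ms <- pmax(40, rgamma(n_blink, shape = 10, scale = bdur_mean / 10))
      len <- pmax(2L, as.integer(round(bdur_ms / 1000 * rate)))
      starts <- integer(0); lens <- integer(0)
      occupied <- integer(0)
      for (b in seq_len(n_blink)) {
        placed <- FALSE
        for (try in 1:50) {
          s <- sample.int(n - len[b] - 2L, 1) + 1L
          span <- (s - 2L):(s + len[b] + 1L)  # 2-sample guard band
          if (!any(span %in% occupied)) {
            occupied <- c(occupied, span)
            starts <- c(starts, s); lens <- c(lens, len[b])
            placed <- TRUE
            break
          }
        }
        if (!placed) next
      }
      if (length(starts)) {
        ord <- order(starts)
        starts <- starts[ord]; lens <- lens[ord]
        idx <- unlist(mapply(function(s, l) s:(s + l - 1L), starts, lens,
                             SIMPLIFY = FALSE))
        xL[idx] <- 0; yL[idx] <- 0; xR[idx] <- 0; yR[idx] <- 0
        blinks <- data.frame(start = (starts - 1L) / rate,
                             end = (starts - 1L + lens) / rate,
                             duration = lens / rate)
      }
    }
    structure(list(t = tt, xL = xL, yL = yL, xR = xR, yR = yR, rate = rate,
                   ledger = list(blinks = blinks, fixations = fixations)),
              class = "gaze_recording")
  })
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat("Gaze recording:", length(x$t), "samples at", x$rate, "Hz (",
      nrow(x$ledger$blinks), "true blinks )\n")
  invisible(x)
}

#' Simulate one session's 21 facial-channel probability series
#'
#' Each channel is i.i.d. Gaussian noise around a session-level mean of
#' `ft_channel_means + ft_impairment_shift * tanh(drive)` plus a
#' session-to-session wander term (`ft_session_sd`), clipped to \[0, 1\].
#' The tanh saturation keeps every channel's systematic mean inside
#' `[mean, mean + shift]` at any impairment level.
#'
#' @inheritParams generate_pvt_session
#' @return An object of class `ft_series`: list with `t` (s), `rate` and a
#'   samples-by-21 `channels` matrix with channel names.
#' @export
generate_ft_series <- function(profile, drive, config, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), drive >= 0)
  n <- round(config$session_duration * config$ft_rate)
  with_seed(seed, {
    mu <- clip01(profile$ft_channel_means +
                   profile$ft_impairment_shift * tanh(drive) +
                   rnorm(21, 0, profile$ft_session_sd))
    ch <- vapply(mu, function(m) {
      clip01(rnorm(n, m, profile$ft_noise_sd))
    }, numeric(n))
    if (n == 1) ch <- matrix(ch, nrow = 1, dimnames = list(NULL, names(mu)))
    structure(list(t = (seq_len(n) - 1) / config$ft_rate,
                   rate = config$ft_rate, channels = ch),
              class = "ft_series")
  })
}

#' Generate a complete synthetic study
#'
#' Simulates every subject-session of the configured study: a PVT event log
#' and (optionally) a gaze recording and facial-channel series per session,
#' with a known ground-truth impairment onset per subject. Roughly
#' `missing_fraction` of subject-sessions are marked missing (technical
#' malfunction) and carry no data. Fixed `config$seed` gives bit-identical
#' output; each subject-session draws from its own substream, so adding
#' subjects or sessions does not perturb earlier draws.
#'
#' @param config A [study_config()].
#' @param signals Character subset of `c("pvt", "gaze", "ft")` to simulate;
#'   dropping the heavy gaze/facial streams speeds up PVT-only experiments.
#' @param onset_hours Ground-truth impairment onset (hours awake), recycled
#'   over subjects.
#' @param profiles Optional list of `n_subjects` [subject_profile()]s; by
#'   default profiles are drawn around the population defaults.
#' @return An object of class `synthetic_study`: list with `config`,
#'   `profiles`, `ground_truth` (onset per subject), `index` (one row per
#'   subject-session with `hours_awake`, `impairment`, `missing`) and
#'   `sessions` (list parallel to `index` rows with elements `pvt`, `gaze`,
#'   `ft`, NULL when missing or not requested).
#' @examples
#' study <- generate_study(study_config(n_subjects = 3, n_sessions = 4,
#'                                      session_duration = 60, seed = 2),
#'                         signals = "pvt")
#' study$index[1:4, ]
#' @export
generate_study <- function(config = study_config(),
                           signals = c("pvt", "gaze", "ft"),
                           onset_hours = 17, profiles = NULL) {
  stopifnot(inherits(config, "study_config"))
  signals <- match.arg(signals, c("pvt", "gaze", "ft"), several.ok = TRUE)
  ns <- config$n_subjects
  if (is.null(profiles)) {
    profiles <- lapply(seq_len(ns), function(s) draw_subject_profile(config, s))
  }
  stopifnot(length(profiles) == ns)
  onset <- rep_len(onset_hours, ns)
  hrs <- hours_awake(config)
  index <- expand.grid(session = seq_len(config$n_sessions),
                       subject = seq_len(ns))[, c("subject", "session")]
  index$hours_awake <- hrs[index$session]
  index$impairment <- impairment_drive(index$hours_awake,
                                       onset[index$subject],
                                       config$session_spacing_h)
  index$excluded <- index$session == 1L  # learning-effect session
  index$missing <- vapply(seq_len(nrow(index)), function(i) {
    with_seed(substream_seed(config$seed, index$subject[i],
                             index$session[i], 2),
              runif(1) < config$missing_fraction)
  }, logical(1))
  sessions <- vector("list", nrow(index))
  for (i in seq_len(nrow(index))) {
    if (index$missing[i]) next
    sub <- index$subject[i]; ses <- index$session[i]
    drv <- index$impairment[i]
    rec <- list()
    if ("pvt" %in% signals) {
      rec$pvt <- generate_pvt_session(profiles[[sub]], drv, config,
                                      substream_seed(config$seed, sub, ses, 3))
    }
    if ("gaze" %in% signals) {
      rec$gaze <- generate_gaze(profiles[[sub]], drv, config,
                                substream_seed(config$seed, sub, ses, 4))
    }
    if ("ft" %in% signals) {
      rec$ft <- generate_ft_series(profiles[[sub]], drv, config,
                                   substream_seed(config$seed, sub, ses, 5))
    }
    sessions[[i]] <- rec
  }
  structure(list(config = config, profiles = profiles,
                 ground_truth = data.frame(subject = seq_len(ns),
                                           onset_hours_awake = onset),
                 index = index, sessions = sessions),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", x$config$n_subjects, "subjects x",
      x$config$n_sessions, "sessions;", sum(x$index$missing),
      "missing sessions\n")
  invisible(x)
}
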