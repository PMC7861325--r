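#' Study design configuration
#'
#' Describes the shape of a sustained-wakefulness study: subjects complete a
#' 10-minute psychomotor vigilance task (PVT) every two hours while gaze and
#' facial channels are recorded. Defaults mirror a 20-subject, 13-session
#' (two-hourly, first session at one hour awake) protocol in which the first
#' session is flagged for exclusion from analysis and roughly 3% of sessions
#' are lost to technical malfunction.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions Number of PVT sessions per subject.
#' @param session_spacing_h Hours between session starts.
#' @param first_session_h Hours awake at the first session.
#' @param session_duration PVT session length in seconds.
#' @param gaze_rate Gaze sampling rate in Hz.
#' @param ft_rate Facial-channel sampling rate in Hz.
#' @param isi_range Two-element numeric, inter-stimulus interval bounds in
#'   seconds (stimuli appear at random intervals within this range).
#' @param missing_fraction Probability that a subject-session is missing.
#' @param seed Master integer seed; all draws are substreams of it.
#'
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(n_subjects = 4, seed = 7)
#' hours_awake(cfg)
#' @export
study_config <- function(n_subjects = 20, n_sessions = 13,
                         session_spacing_h = 2, first_session_h = 1,
                         session_duration = 600, gaze_rate = 50,
                         ft_rate = 30, isi_range = c(2, 10),
                         missing_fraction = 0.03, seed = 1L) {
  stopifnot(length(isi_range) == 2)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (session_duration < 0) stop("session_duration must be >= 0", call. = FALSE)
  if (gaze_rate <= 0) stop("gaze_rate must be > 0", call. = FALSE)
  if (ft_rate <= 0) stop("ft_rate must be > 0", call. = FALSE)
  if (isi_range[1] >= isi_range[2])
    stop("isi_range must satisfy isi_range[1] < isi_range[2]", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    session_spacing_h = session_spacing_h,
    first_session_h = first_session_h,
    session_duration = session_duration,
    gaze_rate = gaze_rate,
    ft_rate = ft_rate,
    isi_range = isi_range,
    missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Hours awake at each session of a study design
#'
#' @param config A [study_config()].
#' @return Numeric vector of length `n_sessions`.
#' @export
hours_awake <- function(config) {
  config$first_session_h +
    config$session_spacing_h * (seq_len(config$n_sessions) - 1)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration:", x$n_subjects, "subjects x", x$n_sessions,
      "sessions (", x$session_spacing_h, "h spacing,",
      x$session_duration, "s PVT )\n")
  cat("  gaze", x$gaze_rate, "Hz | facial channels", x$ft_rate,
      "Hz | ISI", x$isi_range[1], "-", x$isi_range[2], "s | missing",
      sprintf("%.1f%%", 100 * x$missing_fraction), "| seed", x$seed, "\n")
  invisible(x)
}

#' Per-subject behavioural profile for the synthetic generator
#'
#' Parameters governing one subject's simulated reaction times, blinks,
#' fixations and facial channels, and how each responds to the impairment
#' drive (a non-negative scalar, 0 = fully rested; see [generate_study()]).
#' Field shapes are chosen so that increasing impairment moves every index in
#' the direction observed in sleep-deprivation studies: longer and more
#' frequent blinks, longer fixations, more eye closure and mouth opening,
#' less smiling, and more lapses on the PVT.
#'
#' @param baseline_rt_mean Median alert reaction time (ms).
#' @param baseline_rt_sd Spread of the alert RT body (ms).
#' @param lapse_rate_base Baseline probability that a response is a lapse.
#' @param lapse_rate_slope Added lapse probability per unit impairment drive.
#' @param lapse_tail_location Lower bound of the lapse RT tail (ms); lapse
#'   RTs are this value plus a lognormal excess, so some lapses exceed
#'   1000 ms and count as major lapses.
#' @param false_start_rate Expected false starts per session (Poisson).
#' @param blink_dur_base,blink_dur_slope Mean blink duration (ms) when
#'   rested, and its increase per unit impairment.
#' @param blink_freq_base,blink_freq_slope Blink rate (per minute) when
#'   rested, and its increase per unit impairment.
#' @param fix_dur_base,fix_dur_slope Mean fixation duration (ms) when
#'   rested, and its increase per unit impairment.
#' @param blink_dur_session_sd,blink_freq_session_sd,fix_dur_session_sd
#'   Session-to-session wander (SD) of the blink duration (ms), blink rate
#'   (per minute) and fixation duration (ms) around their drive-determined
#'   means — the day-to-day variability that makes real sessions of the
#'   same state differ.
#' @param gaze_jitter Within-fixation coordinate jitter SD (coordinate
#'   units; coordinates live in \[0, 1\]).
#' @param ft_channel_means Named numeric of length 21, resting mean of each
#'   facial channel, in \[0, 1\].
#' @param ft_impairment_shift Named numeric of length 21, signed asymptotic
#'   shift of each channel mean under deep impairment; means move as
#'   `mean + shift * tanh(impairment)` so they stay within
#'   `[mean, mean + shift]`.
#' @param ft_noise_sd Sample-to-sample SD of each facial channel.
#' @param ft_session_sd Session-to-session wander (SD) of each facial
#'   channel's mean.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(baseline_rt_mean = 280, baseline_rt_sd = 40,
                            lapse_rate_base = 0.03, lapse_rate_slope = 0.08,
                            lapse_tail_location = 500,
                            false_start_rate = 0.8,
                            blink_dur_base = 150, blink_dur_slope = 12,
                            blink_freq_base = 14, blink_freq_slope = 1.2,
                            fix_dur_base = 280, fix_dur_slope = 20,
                            blink_dur_session_sd = 10,
                            blink_freq_session_sd = 1.5,
                            fix_dur_session_sd = 15,
                            gaze_jitter = 8e-4,
                            ft_channel_means = default_ft_means(),
                            ft_impairment_shift = default_ft_shifts(),
                            ft_noise_sd = 0.08, ft_session_sd = 0.03) {
  rates <- c(baseline_rt_mean, baseline_rt_sd, lapse_rate_base,
             lapse_rate_slope, false_start_rate, blink_dur_base,
             blink_dur_slope, blink_freq_base, blink_freq_slope,
             fix_dur_base, fix_dur_slope, blink_dur_session_sd,
             blink_freq_session_sd, fix_dur_session_sd, ft_noise_sd,
             ft_session_sd)
  if (any(rates < 0)) stop("profile rates must be >= 0", call. = FALSE)
  ft_channel_means <- ft_channel_means[ft_channels()]
  ft_impairment_shift <- ft_impairment_shift[ft_channels()]
  if (anyNA(ft_channel_means) || anyNA(ft_impairment_shift))
    stop("ft_channel_means and ft_impairment_shift must name all 21 channels",
         call. = FALSE)
  if (any(ft_channel_means < 0 | ft_channel_means > 1))
    stop("ft_channel_means must lie in [0, 1]", call. = FALSE)
  shifted <- ft_channel_means + ft_impairment_shift
  if (any(shifted < 0 | shifted > 1))
    stop("ft_channel_means + ft_impairment_shift must lie in [0, 1]",
         call. = FALSE)
  structure(list(
    baseline_rt_mean = baseline_rt_mean, baseline_rt_sd = baseline_rt_sd,
    lapse_rate_base = lapse_rate_base, lapse_rate_slope = lapse_rate_slope,
    lapse_tail_location = lapse_tail_location,
    false_start_rate = false_start_rate,
    blink_dur_base = blink_dur_base, blink_dur_slope = blink_dur_slope,
    blink_freq_base = blink_freq_base, blink_freq_slope = blink_freq_slope,
    fix_dur_base = fix_dur_base, fix_dur_slope = fix_dur_slope,
    blink_dur_session_sd = blink_dur_session_sd,
    blink_freq_session_sd = blink_freq_session_sd,
    fix_dur_session_sd = fix_dur_session_sd,
    gaze_jitter = gaze_jitter,
    ft_channel_means = ft_channel_means,
    ft_impairment_shift = ft_impairment_shift,
    ft_noise_sd = ft_noise_sd, ft_session_sd = ft_session_sd
  ), class = "subject_profile")
}

#' Default resting means of the 21 facial channels
#'
#' Plausible resting levels for an attentive seated subject: high attention,
#' neutral valence near 0.5, head pose and interocular distance mid-range,
#' and low activation of individual action units.
#'
#' @return Named numeric vector of length 21.
#' @export
default_ft_means <- function() {
  setNames(c(
    brow_furrow = 0.10, brow_raise = 0.12, engagement = 0.30,
    lip_corner_depressor = 0.08, smile = 0.10, valence = 0.50,
    attention = 0.85, interocular_distance = 0.50, pitch = 0.45,
    yaw = 0.50, roll = 0.50, inner_brow_raise = 0.10, eye_closure = 0.15,
    nose_wrinkle = 0.06, upper_lip_raise = 0.07, lip_suck = 0.08,
    lip_press = 0.09, mouth_open = 0.12, chin_raise = 0.07, smirk = 0.06,
    lip_pucker = 0.08
  )[ft_channels()], ft_channels())
}

#' Default impairment shifts of the 21 facial channels
#'
#' Signed asymptotic change of each channel mean under deep impairment.
#' Signs follow the directions reported for sleep-deprived subjects: eye
#' closure, brow raise, mouth open, lip pucker, inner brow raise, lip press,
#' head pitch and nose wrinkle increase; smile and head roll decrease;
#' channels with no reliable class difference get near-zero shifts.
#'
#' @return Named numeric vector of length 21.
#' @export
default_ft_shifts <- function() {
  setNames(c(
    brow_furrow = 0.001, brow_raise = 0.030, engagement = 0.008,
    lip_corner_depressor = 0.010, smile = -0.020, valence = 0.003,
    attention = 0.015, interocular_distance = 0.003, pitch = 0.020,
    yaw = -0.006, roll = -0.010, inner_brow_raise = 0.020,
    eye_closure = 0.040, nose_wrinkle = 0.012, upper_lip_raise = 0.010,
    lip_suck = -0.002, lip_press = 0.015, mouth_open = 0.025,
    chin_raise = 0.006, smirk = 0.008, lip_pucker = 0.020
  )[ft_channels()], ft_channels())
}

# Draw a subject's profile around the population defaults (its own
# substream, so profiles are stable under changes to other subjects).
draw_subject_profile <- function(config, subject) {
  with_seed(substream_seed(config$seed, subject, 0, 1), {
    means <- clip01(default_ft_means() + rnorm(21, 0, 0.04))
    names(means) <- ft_channels()
    shifts <- default_ft_shifts()
    # keep means + shifts inside [0, 1] after subject jitter
    means <- pmin(pmax(means, pmax(0, -shifts)), pmin(1, 1 - pmax(0, shifts)))
    subject_profile(
      baseline_rt_mean = rnorm(1, 280, 15),
      baseline_rt_sd = runif(1, 30, 50),
      lapse_rate_base = runif(1, 0.02, 0.05),
      false_start_rate = runif(1, 0.4, 1.4),
      blink_dur_base = rnorm(1, 150, 15),
      blink_freq_base = rnorm(1, 14, 2),
      fix_dur_base = rnorm(1, 280, 25),
      ft_channel_means = means,
      ft_impairment_shift = shifts
    )
  })
}
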