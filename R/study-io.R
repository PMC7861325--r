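#' Write a synthetic study to disk as plain-text files
#'
#' One directory per subject; per session a gaze CSV (`t_s, xL, yL, xR, yR`),
#' a facial CSV (`t_s` plus the 21 named channels) and a PVT CSV
#' (`event_type, t_s, rt_ms` with `event_type` one of `stimulus`,
#' `response`, `false_start`), plus a study-level `ground_truth.json`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(ground_truth = study$ground_truth,
         index = study$index),
    file.path(dir, "ground_truth.json"), dataframe = "columns",
    auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nrow(study$index))) {
    if (study$index$missing[i]) next
    sub <- study$index$subject[i]; ses <- study$index$session[i]
    sdir <- file.path(dir, sprintf("subject_%02d", sub))
    dir.create(sdir, showWarnings = FALSE)
    rec <- study$sessions[[i]]
    tag <- sprintf("session_%02d", ses)
    if (!is.null(rec$pvt)) {
      log <- rec$pvt
      ev <- rbind(
        data.frame(event_type = rep("stimulus", length(log$stimulus_times)),
                   t_s = log$stimulus_times,
                   rt_ms = rep(NA_real_, length(log$stimulus_times))),
        data.frame(event_type = rep("response", length(log$rts)),
                   t_s = log$stimulus_times + log$rts / 1000,
                   rt_ms = log$rts),
        data.frame(event_type = rep("false_start",
                                    length(log$false_start_times)),
                   t_s = log$false_start_times,
                   rt_ms = rep(NA_real_, length(log$false_start_times))))
      ev <- ev[order(ev$t_s), ]
      write.csv(ev, file.path(sdir, paste0(tag, "_pvt.csv")),
                row.names = FALSE)
    }
    if (!is.null(rec$gaze)) {
      g <- rec$gaze
      write.csv(data.frame(t_s = g$t, xL = g$xL, yL = g$yL,
                           xR = g$xR, yR = g$yR),
                file.path(sdir, paste0(tag, "_gaze.csv")), row.names = FALSE)
    }
    if (!is.null(rec$ft)) {
      f <- rec$ft
      df <- cbind(data.frame(t_s = f$t), as.data.frame(f$channels))
      write.csv(df, file.path(sdir, paste0(tag, "_ft.csv")),
                row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a gaze CSV into a gaze recording
#'
#' Expects the dialect written by [write_study()]: columns `t_s, xL, yL,
#' xR, yR` at a fixed sampling rate.
#'
#' @param path CSV path.
#' @return A `gaze_recording`.
#' @export
read_gaze_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("t_s", "xL", "yL", "xR", "yR") %in% names(d)))
  rate <- if (nrow(d) > 1) 1 / median(diff(d$t_s)) else NA_real_
  structure(list(t = d$t_s, xL = d$xL, yL = d$yL, xR = d$xR, yR = d$yR,
                 rate = rate, ledger = NULL),
            class = "gaze_recording")
}

#' Read a facial-channel CSV into an ft series
#'
#' @param path CSV path with columns `t_s` plus the 21 channels of
#'   [ft_channels()].
#' @return An `ft_series`.
#' @export
read_ft_csv <- function(path) {
  d <- read.csv(path)
  stopifnot("t_s" %in% names(d), all(ft_channels() %in% names(d)))
  rate <- if (nrow(d) > 1) 1 / median(diff(d$t_s)) else NA_real_
  structure(list(t = d$t_s, rate = rate,
                 channels = as.matrix(d[, ft_channels()])),
            class = "ft_series")
}

#' Read a PVT event CSV into a PVT log
#'
#' @param path CSV path with columns `event_type, t_s, rt_ms`.
#' @param duration Session duration in seconds (defaults to the last event
#'   time rounded up).
#' @return A `pvt_log`.
#' @export
read_pvt_csv <- function(path, duration = NULL) {
  d <- read.csv(path)
  stopifnot(all(c("event_type", "t_s", "rt_ms") %in% names(d)))
  stim <- d[d$event_type == "stimulus", , drop = FALSE]
  resp <- d[d$event_type == "response", , drop = FALSE]
  fs <- d[d$event_type == "false_start", , drop = FALSE]
  structure(list(stimulus_times = stim$t_s,
                 rts = resp$rt_ms[order(resp$t_s)],
                 false_start_times = fs$t_s,
                 duration = duration %||% ceiling(max(d$t_s, 0)),
                 lapse_draws = NULL),
            class = "pvt_log")
}
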