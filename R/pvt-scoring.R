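#' PVT scoring parameters
#'
#' @param lapse_ms Reaction-time cutoff for a lapse (ms, strict `>`).
#' @param major_lapse_ms Cutoff for a major lapse (ms, strict `>`).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(lapse_ms = 500, major_lapse_ms = 1000) {
  if (!(major_lapse_ms > lapse_ms && lapse_ms > 0))
    stop("need major_lapse_ms > lapse_ms > 0", call. = FALSE)
  structure(list(lapse_ms = lapse_ms, major_lapse_ms = major_lapse_ms),
            class = "scoring_params")
}

#' Score one PVT session
#'
#' The session score is the combined count of lapses (RT strictly above
#' 500 ms), major lapses (RT strictly above 1000 ms) and false starts.
#' A response above 1000 ms is both a lapse and a major lapse, so major
#' lapses carry double weight in the score.
#'
#' @param log A `pvt_log`.
#' @param params A [scoring_params()].
#' @return An object of class `pvt_score`: list with `n_lapses`, `n_major`,
#'   `n_false_starts` and `score`.
#' @examples
#' log <- structure(list(rts = c(450, 600, 1200),
#'                       false_start_times = 1), class = "pvt_log")
#' score_session(log)$score  # 2 lapses + 1 major + 1 false start = 4
#' @export
score_session <- function(log, params = scoring_params()) {
  if (any(log$rts < 0)) stop("reaction times must be >= 0", call. = FALSE)
  n_lapses <- sum(log$rts > params$lapse_ms)
  n_major <- sum(log$rts > params$major_lapse_ms)
  n_fs <- length(log$false_start_times)
  structure(list(n_lapses = n_lapses, n_major = n_major,
                 n_false_starts = n_fs,
                 score = n_lapses + n_major + n_fs),
            class = "pvt_score")
}

#' Euclidean-normalize one subject's session scores
#'
#' Each non-missing score is divided by the Euclidean norm of the subject's
#' non-missing scores, adjusting for scale differences between subjects.
#' Missing sessions (`NA`) are excluded from the norm and stay missing.
#'
#' @param scores Numeric vector of one subject's session scores, `NA` for
#'   missing sessions.
#' @return Numeric vector of the same length with unit Euclidean norm over
#'   the non-missing entries (zeros, with a warning, if all scores are 0).
#' @examples
#' normalize_scores(c(3, 4, 0, 0))  # c(0.6, 0.8, 0, 0)
#' @export
normalize_scores <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stop("need at least one non-missing score", call. = FALSE)
  nrm <- sqrt(sum(scores[ok]^2))
  if (nrm == 0) {
    warning("all scores are zero; norm undefined, returning zeros",
            call. = FALSE)
    return(scores)
  }
  scores / nrm
}

#' Score every session of a study
#'
#' Applies [score_session()] to each non-missing session, excludes session 1
#' (learning effects) from the output, and Euclidean-normalizes each
#' subject's remaining scores.
#'
#' @param study A [generate_study()] result containing PVT logs.
#' @param params A [scoring_params()].
#' @return Data frame with one row per analyzed non-missing session:
#'   `subject`, `session`, `hours_awake`, `n_lapses`, `n_major`,
#'   `n_false_starts`, `score`, `normalized_score`.
#' @export
score_study <- function(study, params = scoring_params()) {
  idx <- study$index
  rows <- which(!idx$missing & !idx$excluded)
  sc <- lapply(rows, function(i) {
    log <- study$sessions[[i]]$pvt
    if (is.null(log)) stop("study lacks PVT logs", call. = FALSE)
    s <- score_session(log, params)
    data.frame(subject = idx$subject[i], session = idx$session[i],
               hours_awake = idx$hours_awake[i],
               n_lapses = s$n_lapses, n_major = s$n_major,
               n_false_starts = s$n_false_starts, score = s$score)
  })
  out <- do.call(rbind, sc)
  out$normalized_score <- NA_real_
  for (sub in unique(out$subject)) {
    r <- out$subject == sub
    out$normalized_score[r] <- suppressWarnings(normalize_scores(out$score[r]))
  }
  rownames(out) <- NULL
  out
}
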