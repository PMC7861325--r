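#' One-way ANOVA of normalized PVT scores across sessions
#'
#' Standard one-way ANOVA treating each session as a group (unbalanced
#' groups allowed). Sessions with fewer than two observations are excluded
#' with a warning.
#'
#' @param table Session score table with columns `session` and
#'   `normalized_score` (see [score_study()]).
#' @return List with `F`, `df_between`, `df_within`, `p` and the retained
#'   `sessions`.
#' @export
anova_sessions <- function(table) {
  counts <- table(factor(table$session))
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding session(s) with < 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    table <- table[!table$session %in% as.numeric(small), , drop = FALSE]
  }
  sessions <- sort(unique(table$session))
  if (length(sessions) < 2)
    stop("need >= 2 sessions with >= 2 observations each", call. = FALSE)
  fit <- lm(normalized_score ~ factor(session), data = table)
  an <- anova(fit)
  list(F = an$`F value`[1], df_between = an$Df[1], df_within = an$Df[2],
       p = an$`Pr(>F)`[1], sessions = sessions)
}

#' Tukey-Kramer pairwise session comparisons
#'
#' Studentized-range based pairwise p-values with the Tukey-Kramer
#' unequal-n correction, arranged as a symmetric matrix with unit diagonal.
#'
#' @inheritParams anova_sessions
#' @return Symmetric matrix of adjusted p-values, dimnames = session ids.
#' @export
tukey_kramer <- function(table) {
  counts <- table(factor(table$session))
  table <- table[!table$session %in%
                   as.numeric(names(counts)[counts < 2]), , drop = FALSE]
  table$session_f <- factor(table$session)
  fit <- aov(normalized_score ~ session_f, data = table)
  tk <- TukeyHSD(fit)$session_f
  lv <- levels(table$session_f)
  p <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    a <- pair[[i]][1]; b <- pair[[i]][2]
    p[a, b] <- tk[i, "p adj"]
    p[b, a] <- tk[i, "p adj"]
  }
  p
}

#' Derive the normal/impaired threshold from group session statistics
#'
#' Finds the impairment onset: the earliest session whose mean normalized
#' PVT score exceeds every baseline session's mean *and* differs from every
#' baseline session at the Tukey-Kramer `p < alpha` level. The threshold
#' tau is the across-subject mean normalized score of that onset session;
#' observations strictly above tau are later labeled impaired.
#'
#' The baseline defaults to the first three analyzed sessions, which fall
#' within the initial stable window of wakefulness.
#'
#' @inheritParams anova_sessions
#' @param baseline_sessions Session ids forming the rested baseline
#'   (default: the first three analyzed sessions).
#' @param alpha Significance level for the pairwise comparisons.
#' @return An object of class `impairment_threshold`: list with `status`
#'   (`"impairment detected"` or `"no impairment detected"`),
#'   `onset_session`, `onset_hours_awake` (if available), `tau`, `anova`,
#'   `pairwise_p`, `baseline_sessions`, `session_means` and `alpha`.
#'   `onset_session` and `tau` are `NA` when no onset is found.
#' @export
derive_threshold <- function(table, baseline_sessions = NULL, alpha = 0.05) {
  an <- anova_sessions(table)
  pw <- tukey_kramer(table)
  sessions <- an$sessions
  if (is.null(baseline_sessions))
    baseline_sessions <- head(sessions, 3)
  if (!all(baseline_sessions %in% sessions))
    stop("baseline_sessions must be analyzed sessions", call. = FALSE)
  means <- vapply(sessions, function(s) {
    mean(table$normalized_score[table$session == s])
  }, numeric(1))
  names(means) <- sessions
  base_means <- means[as.character(baseline_sessions)]
  candidates <- setdiff(sessions, baseline_sessions)
  onset <- NA_real_
  for (s in candidates) {
    sig <- all(pw[as.character(s), as.character(baseline_sessions)] < alpha)
    if (sig && all(means[as.character(s)] > base_means)) {
      onset <- s
      break
    }
  }
  tau <- if (is.na(onset)) NA_real_ else unname(means[as.character(onset)])
  onset_hours <- if (!is.na(onset) && "hours_awake" %in% names(table)) {
    table$hours_awake[match(onset, table$session)]
  } else NA_real_
  structure(list(
    status = if (is.na(onset)) "no impairment detected"
             else "impairment detected",
    onset_session = onset, onset_hours_awake = onset_hours, tau = tau,
    anova = an, pairwise_p = pw, baseline_sessions = baseline_sessions,
    session_means = means, alpha = alpha
  ), class = "impairment_threshold")
}

#' @export
print.impairment_threshold <- function(x, ...) {
  cat("Impairment threshold:", x$status, "\n")
  if (!is.na(x$onset_session)) {
    cat(sprintf("  onset session %s (%s h awake), tau = %.4f\n",
                x$onset_session,
                ifelse(is.na(x$onset_hours_awake), "?", x$onset_hours_awake),
                x$tau))
  }
  cat(sprintf("  ANOVA F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}

#' Label observations as normal or impaired
#'
#' An observation is impaired iff its normalized score is strictly above
#' tau; a score exactly equal to tau is normal. Rows with a missing score
#' are dropped with a message.
#'
#' @param table Session score table (see [score_study()]).
#' @param tau Threshold, or an `impairment_threshold` object.
#' @return The table with an added factor column `label` with levels
#'   `c("normal", "impaired")`.
#' @export
label_observations <- function(table, tau) {
  if (inherits(tau, "impairment_threshold")) tau <- tau$tau
  if (is.na(tau)) stop("tau is undefined (no impairment detected)",
                       call. = FALSE)
  drop <- is.na(table$normalized_score)
  if (any(drop)) {
    message("dropping ", sum(drop), " observation(s) with missing score")
    table <- table[!drop, , drop = FALSE]
  }
  table$label <- factor(ifelse(table$normalized_score > tau,
                               "impaired", "normal"),
                        levels = c("normal", "impaired"))
  table
}

#' Assemble the labeled dataset for classification
#'
#' Joins the per-session feature table with the labeled score table by
#' subject and session, keeping the 25 features, the subject id (the LOSO
#' grouping key) and the label.
#'
#' @param features Feature table from [extract_features()].
#' @param labeled Labeled score table from [label_observations()].
#' @param impute Impute flagged-missing feature values as 0 (default TRUE).
#' @return Data frame with `subject`, `session`, `label` and the 25 feature
#'   columns.
#' @export
build_labeled_dataset <- function(features, labeled, impute = TRUE) {
  out <- merge(labeled[, c("subject", "session", "label")], features,
               by = c("subject", "session"))
  out <- out[order(out$subject, out$session), , drop = FALSE]
  if (impute) out <- impute_missing_features(out)
  rownames(out) <- NULL
  out
}
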