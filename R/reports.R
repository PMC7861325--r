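#' Write the impairment threshold to JSON
#'
#' @param threshold An `impairment_threshold` (see [derive_threshold()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(threshold, path) {
  jsonlite::write_json(list(
    status = threshold$status,
    onset_session = threshold$onset_session,
    onset_hours_awake = threshold$onset_hours_awake,
    tau = threshold$tau,
    anova = threshold$anova[c("F", "df_between", "df_within", "p")],
    baseline_sessions = threshold$baseline_sessions,
    alpha = threshold$alpha
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a feature-selection result to JSON
#'
#' @param subset A `feature_subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(subset, path) {
  jsonlite::write_json(list(
    method = subset$method, features = subset$features,
    objective_value = subset$objective_value,
    trajectory = subset$trajectory, seed = subset$seed
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write the ranked index report to CSV
#'
#' @param stats An [index_stats()] table.
#' @param path Output path.
#' @param alpha Significance level for the report flags.
#' @return `path`, invisibly.
#' @export
write_index_report_csv <- function(stats, path, alpha = 0.05) {
  write.csv(rank_report(stats, alpha), path, row.names = FALSE)
  invisible(path)
}

#' Write the evaluation grid's metric tables to CSV
#'
#' Emits `<stem>_ba.csv`, `<stem>_sensitivity.csv`, `<stem>_specificity.csv`
#' and `<stem>_bias.csv`.
#'
#' @param grid An `eval_grid` (see [run_grid()]).
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_grid_csv <- function(grid, stem) {
  for (m in c("ba", "sensitivity", "specificity", "bias")) {
    write.csv(data.frame(classifier = rownames(grid[[m]]), grid[[m]],
                         check.names = FALSE),
              paste0(stem, "_", m, ".csv"), row.names = FALSE)
  }
  invisible(stem)
}
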