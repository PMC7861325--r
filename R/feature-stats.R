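#' Welch's unequal-variance t-test between classes
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom. The
#' sign convention is `mean(normal) - mean(impaired)`: indices that are
#' larger under impairment (e.g., blink duration) get a negative t.
#'
#' @param x_normal,x_impaired Numeric samples (>= 2 values each, and not
#'   both constant).
#' @return List with `t`, `df` and `p`.
#' @export
welch_t <- function(x_normal, x_impaired) {
  if (length(x_normal) < 2 || length(x_impaired) < 2)
    stop("both samples need >= 2 values", call. = FALSE)
  if (var(x_normal) == 0 && var(x_impaired) == 0)
    stop("both samples have zero variance", call. = FALSE)
  ht <- t.test(x_normal, x_impaired, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fisher score of a single feature
#'
#' Ratio of between-class to within-class scatter: larger values mean the
#' two class distributions are further apart in this feature. The default
#' (grand-mean) form is
#' `F = (n0 (mu0 - mu)^2 + n1 (mu1 - mu)^2) / (n0 s0^2 + n1 s1^2)` with
#' class means `mu0`, `mu1`, grand mean `mu` and class variances `s0^2`,
#' `s1^2`; the `two_class` variant is `(mu0 - mu1)^2 / (s0^2 + s1^2)`.
#' Both are invariant to affine transforms of the feature and to label
#' relabeling.
#'
#' @param x Feature values.
#' @param labels Binary class labels (two levels required).
#' @param variant `"grand_mean"` (default) or `"two_class"`.
#' @param var_floor Floor applied to the denominator to avoid division by
#'   zero on degenerate features.
#' @return Non-negative Fisher score.
#' @export
fisher_score <- function(x, labels, variant = c("grand_mean", "two_class"),
                         var_floor = 1e-12) {
  variant <- match.arg(variant)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("labels must contain exactly two classes", call. = FALSE)
  labels <- droplevels(labels)
  x0 <- x[labels == levels(labels)[1]]
  x1 <- x[labels == levels(labels)[2]]
  n0 <- length(x0); n1 <- length(x1)
  m0 <- mean(x0); m1 <- mean(x1); m <- mean(x)
  v0 <- if (n0 > 1) var(x0) * (n0 - 1) / n0 else 0
  v1 <- if (n1 > 1) var(x1) * (n1 - 1) / n1 else 0
  if (variant == "grand_mean") {
    num <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
    den <- max(n0 * v0 + n1 * v1, var_floor)
  } else {
    num <- (m0 - m1)^2
    den <- max(v0 + v1, var_floor)
  }
  num / den
}

#' Per-index class statistics
#'
#' Computes the Welch t (normal minus impaired), Welch-Satterthwaite df,
#' two-sided p and Fisher score of every feature column.
#'
#' @param data Labeled dataset (see [build_labeled_dataset()]) with a
#'   `label` factor and the 25 feature columns.
#' @param alpha Significance level for the `significant` flag.
#' @param variant Fisher-score variant, see [fisher_score()].
#' @return Data frame of class `index_stats`: one row per feature with
#'   columns `index`, `t`, `df`, `p`, `fisher`, `significant`.
#' @export
index_stats <- function(data, alpha = 0.05,
                        variant = c("grand_mean", "two_class")) {
  variant <- match.arg(variant)
  fcols <- intersect(feature_names(), names(data))
  if (!length(fcols)) stop("no feature columns found", call. = FALSE)
  normal <- data$label == "normal"
  rows <- lapply(fcols, function(f) {
    wt <- welch_t(data[[f]][normal], data[[f]][!normal])
    data.frame(index = f, t = wt$t, df = wt$df, p = wt$p,
               fisher = fisher_score(data[[f]], data$label, variant),
               significant = wt$p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_stats", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Ranked index report with Bonferroni flags
#'
#' Orders the indices by |t| descending and flags significance at `alpha`
#' and at the Bonferroni-corrected level `alpha / n_indices` (0.002 for 25
#' indices at alpha 0.05). Degrees of freedom are rounded to integers for
#' display.
#'
#' @param stats An [index_stats()] table.
#' @param alpha Uncorrected significance level.
#' @param bonferroni Include the Bonferroni flag column.
#' @return Data frame sorted by |t| with columns `index`, `t`, `df`, `p`,
#'   `fisher`, `sig_alpha` and (optionally) `sig_bonferroni`; the cutoff is
#'   stored in `attr(, "bonferroni_cutoff")`.
#' @export
rank_report <- function(stats, alpha = 0.05, bonferroni = TRUE) {
  out <- stats[order(-abs(stats$t), stats$index), , drop = FALSE]
  out$df <- round(out$df)
  out$sig_alpha <- out$p < alpha
  cutoff <- alpha / nrow(out)
  if (bonferroni) out$sig_bonferroni <- out$p < cutoff
  out$significant <- NULL
  rownames(out) <- NULL
  attr(out, "bonferroni_cutoff") <- cutoff
  class(out) <- "data.frame"
  out
}
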