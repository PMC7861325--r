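#' Balanced accuracy: geometric mean of sensitivity and specificity
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @return `sqrt(sensitivity * specificity)`.
#' @examples
#' balanced_accuracy(1.0, 0.5)    # ~0.707
#' balanced_accuracy(0.863, 0.771)  # ~0.816
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sqrt(sensitivity * specificity)
}

#' Classification metrics from confusion counts
#'
#' Impaired is the positive class: sensitivity = tp / (tp + fn),
#' specificity = tn / (tn + fp), balanced accuracy their geometric mean,
#' and bias = sensitivity - specificity (large |bias| flags class-skewed
#' predictions).
#'
#' @param tp,fn,tn,fp Confusion counts, or a list with those names as the
#'   first argument.
#' @return List with `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `bias` and the counts.
#' @export
metrics_from_confusion <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.list(tp)) {
    c_ <- tp; tp <- c_$tp; fn <- c_$fn; tn <- c_$tn; fp <- c_$fp
  }
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("test set lacks one class entirely", call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = balanced_accuracy(sens, spec),
       bias = sens - spec, tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Balance a training set by random undersampling
#'
#' Rows of the majority class are randomly dropped (without replacement)
#' until both classes have exactly the minority-class count; minority rows
#' are untouched.
#'
#' @param data Labeled dataset with a `label` factor column.
#' @param seed Integer seed.
#' @return The balanced data frame.
#' @export
undersample_balance <- function(data, seed = NULL) {
  counts <- table(data$label)
  if (any(counts == 0)) stop("training set contains a single class",
                             call. = FALSE)
  m <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(data$label == cl)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
    data[sort(keep), , drop = FALSE]
  })
}

#' Evaluation configuration for the LOSO grid
#'
#' @param n_iterations Undersampling iterations (results pooled; default 5).
#' @param seed Master seed; all folds, undersamples and stochastic fits use
#'   substreams of it.
#' @param standardize Z-score the features with training-fold statistics
#'   before fitting (default TRUE; distance-based models need a stated
#'   scale convention).
#' @param wrapper_mode `"nested"` selects wrapper features inside each
#'   training fold (leakage-free, default); `"paper"` selects once on the
#'   full dataset before the final cross-validation.
#' @param wrapper_iterations Undersampling iterations used inside the
#'   wrapper objective (default 1, keeping the search affordable).
#' @param max_features Feature budget for selection (default 12, one
#'   feature per 20 planned observations; see [max_feature_budget()]).
#' @param alpha Significance level for the t filter.
#' @param ga Named list of GA overrides (population, generations, ...).
#' @param aggregate `"pooled"` pools confusion counts over folds and
#'   iterations (default, exactly reconstructible); `"averaged"` averages
#'   per-iteration metrics instead.
#' @param classifier_params Named list of per-classifier hyperparameter
#'   overrides passed to [fit_classifier()].
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_iterations = 5, seed = 1, standardize = TRUE,
                        wrapper_mode = c("nested", "paper"),
                        wrapper_iterations = 1, max_features = 12,
                        alpha = 0.05, ga = list(),
                        aggregate = c("pooled", "averaged"),
                        classifier_params = list()) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), standardize = standardize,
                 wrapper_mode = match.arg(wrapper_mode),
                 wrapper_iterations = as.integer(wrapper_iterations),
                 max_features = as.integer(max_features), alpha = alpha,
                 ga = ga, aggregate = match.arg(aggregate),
                 classifier_params = classifier_params),
            class = "eval_config")
}

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mean = mu, sd = sdev)
}

apply_standardizer <- function(X, sc) {
  sweep(sweep(X, 2, sc$mean), 2, sc$sd, "/")
}

feature_matrix <- function(data, features) {
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Leave-one-subject-out evaluation of one classifier
#'
#' For each of `n_iterations` undersampling draws and each subject: train
#' on the balanced rows of all other subjects (features standardized with
#' training statistics only) and predict the held-out subject's rows.
#' Confusion counts are pooled over all subjects and iterations, so every
#' subject appears as the test subject exactly `n_iterations` times and the
#' pooled totals equal `n_iterations` times the class row counts.
#'
#' @param classifier One of [classifier_ids()].
#' @param data Labeled dataset ([build_labeled_dataset()]); must contain a
#'   `subject` column, a binary `label` factor and the feature columns.
#' @param features Feature names to use (default: all 25).
#' @param config An [eval_config()].
#' @return An object of class `loso_result`: the pooled `metrics`, the
#'   pooled `counts` and a per-fold `folds` data frame.
#' @export
loso_evaluate <- function(classifier, data, features = NULL,
                          config = eval_config()) {
  features <- features %||% intersect(feature_names(), names(data))
  if (inherits(features, "feature_subset")) features <- features$features
  subjects <- sort(unique(data$subject))
  if (length(subjects) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (nlevels(droplevels(data$label)) < 2)
    stop("both classes must be present", call. = FALSE)
  folds <- list()
  for (iter in seq_len(config$n_iterations)) {
    for (si in seq_along(subjects)) {
      sub <- subjects[si]
      test <- data[data$subject == sub, , drop = FALSE]
      if (nrow(test) == 0) {
        message("subject ", sub, " has zero rows; skipped")
        next
      }
      train <- data[data$subject != sub, , drop = FALSE]
      bal <- undersample_balance(
        train, seed = substream_seed(config$seed, iter, si, 7))
      Xtr <- feature_matrix(bal, features)
      Xte <- feature_matrix(test, features)
      if (config$standardize) {
        sc <- fit_standardizer(Xtr)
        Xtr <- apply_standardizer(Xtr, sc)
        Xte <- apply_standardizer(Xte, sc)
      }
      model <- fit_classifier(classifier, Xtr, droplevels(bal$label),
                              params = config$classifier_params,
                              seed = substream_seed(config$seed, iter, si, 8))
      pred <- predict_classifier(model, Xte)
      truth <- test$label
      folds[[length(folds) + 1L]] <- data.frame(
        iteration = iter, subject = sub,
        tp = sum(pred == "impaired" & truth == "impaired"),
        fn = sum(pred == "normal" & truth == "impaired"),
        tn = sum(pred == "normal" & truth == "normal"),
        fp = sum(pred == "impaired" & truth == "normal"))
    }
  }
  folds <- do.call(rbind, folds)
  counts <- list(tp = sum(folds$tp), fn = sum(folds$fn),
                 tn = sum(folds$tn), fp = sum(folds$fp))
  metrics <- if (config$aggregate == "pooled") {
    metrics_from_confusion(counts)
  } else {
    per <- lapply(split(folds, folds$iteration), function(fi) {
      metrics_from_confusion(list(tp = sum(fi$tp), fn = sum(fi$fn),
                                  tn = sum(fi$tn), fp = sum(fi$fp)))
    })
    ms <- c("sensitivity", "specificity", "balanced_accuracy", "bias")
    av <- lapply(ms, function(m) mean(vapply(per, `[[`, numeric(1), m)))
    names(av) <- ms
    c(av, counts)
  }
  structure(list(classifier = classifier, features = features,
                 metrics = metrics, counts = counts, folds = folds),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s (%d features): BA %.3f | sens %.3f | spec %.3f | bias %+.3f\n",
              x$classifier, length(x$features), m$balanced_accuracy,
              m$sensitivity, m$specificity, m$bias))
  invisible(x)
}

#' Wrapper objective: LOSO balanced accuracy of a feature subset
#'
#' Builds the objective maximized by the SFS and GA wrappers: the balanced
#' accuracy of `classifier` under leave-one-subject-out evaluation of the
#' given rows, at `wrapper_iterations` undersampling iterations. Subsets
#' whose evaluation fails (e.g., a singular covariance) score 0.
#'
#' @param data Labeled dataset (the rows the wrapper may look at — the full
#'   dataset in `"paper"` mode, the training fold in `"nested"` mode).
#' @param classifier One of [classifier_ids()].
#' @param config An [eval_config()].
#' @return Function mapping a character vector of features to a scalar.
#' @export
wrapper_objective <- function(data, classifier, config = eval_config()) {
  inner <- eval_config(n_iterations = config$wrapper_iterations,
                       seed = substream_seed(config$seed, 17),
                       standardize = config$standardize,
                       classifier_params = config$classifier_params)
  function(features) {
    if (!length(features)) return(0)
    tryCatch(
      loso_evaluate(classifier, data, features, inner)$metrics$balanced_accuracy,
      error = function(e) 0)
  }
}
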