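select_wrapper <- function(method, data, classifier, config, seed) {
  obj <- wrapper_objective(data, classifier, config)
  if (method == "sfs") {
    select_sfs(obj, intersect(feature_names(), names(data)),
               config$max_features)
  } else {
    do.call(select_ga, c(list(objective = obj,
                              features = intersect(feature_names(),
                                                   names(data)),
                              max_features = config$max_features,
                              seed = seed),
                         config$ga))
  }
}

# Nested-wrapper LOSO: features are selected inside each training fold
# (selection never sees the held-out subject), once per fold, and reused
# across the undersampling iterations.
loso_evaluate_nested <- function(classifier, data, method, config) {
  features_all <- intersect(feature_names(), names(data))
  subjects <- sort(unique(data$subject))
  folds <- list()
  fold_features <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    test <- data[data$subject == sub, , drop = FALSE]
    train <- data[data$subject != sub, , drop = FALSE]
    subset <- select_wrapper(method, train, classifier, config,
                             seed = substream_seed(config$seed, si, 21))
    fold_features[[si]] <- subset$features
    for (iter in seq_len(config$n_iterations)) {
      bal <- undersample_balance(
        train, seed = substream_seed(config$seed, iter, si, 7))
      Xtr <- feature_matrix(bal, subset$features)
      Xte <- feature_matrix(test, subset$features)
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
  structure(list(classifier = classifier, features = features_all,
                 fold_features = fold_features,
                 metrics = metrics_from_confusion(counts),
                 counts = counts, folds = folds),
            class = "loso_result")
}

#' Run the full classifier-by-selector evaluation grid
#'
#' Evaluates every (classifier, feature-selection) combination under
#' leave-one-subject-out cross-validation with balanced undersampling.
#' Filter selections are computed once from the full-data index statistics;
#' wrapper selections follow `config$wrapper_mode` (nested per training
#' fold by default, or once on the full dataset in `"paper"` mode). A cell
#' whose evaluation fails is recorded as missing and the run continues.
#'
#' @param data Labeled dataset ([build_labeled_dataset()]).
#' @param classifiers Classifier ids to evaluate (default: all 14).
#' @param selectors Selection regimes among
#'   `c("all", "t_filter", "fisher_filter", "sfs", "ga")`.
#' @param config An [eval_config()].
#' @return An object of class `eval_grid`: list with matrices `ba`,
#'   `sensitivity`, `specificity`, `bias` (classifier by selector), the
#'   per-cell `cells` list, the index `stats` and the `config`.
#' @export
run_grid <- function(data, classifiers = classifier_ids(),
                     selectors = c("all", "t_filter", "fisher_filter",
                                   "sfs", "ga"),
                     config = eval_config()) {
  classifiers <- match.arg(classifiers, classifier_ids(), several.ok = TRUE)
  selectors <- match.arg(selectors,
                         c("all", "t_filter", "fisher_filter", "sfs", "ga"),
                         several.ok = TRUE)
  stats <- index_stats(data, alpha = config$alpha)
  subsets <- list(all = new_feature_subset(
    "all", intersect(feature_names(), names(data))))
  if ("t_filter" %in% selectors)
    subsets$t_filter <- select_filter_t(stats, config$max_features,
                                        config$alpha)
  if ("fisher_filter" %in% selectors)
    subsets$fisher_filter <- select_filter_fisher(stats, config$max_features)
  mk <- function() matrix(NA_real_, length(classifiers), length(selectors),
                          dimnames = list(classifiers, selectors))
  ba <- mk(); sens <- mk(); spec <- mk(); bias <- mk()
  cells <- list()
  for (cl in classifiers) {
    for (sel in selectors) {
      res <- tryCatch({
        if (sel %in% c("sfs", "ga")) {
          if (config$wrapper_mode == "nested") {
            loso_evaluate_nested(cl, data, sel, config)
          } else {
            subset <- select_wrapper(sel, data, cl, config,
                                     seed = substream_seed(config$seed, 23))
            out <- loso_evaluate(cl, data, subset$features, config)
            out$selection <- subset
            out
          }
        } else {
          loso_evaluate(cl, data, subsets[[sel]]$features, config)
        }
      }, error = function(e) {
        message("cell ", cl, " x ", sel, " failed: ", conditionMessage(e))
        NULL
      })
      cells[[paste(cl, sel, sep = ".")]] <- res
      if (!is.null(res)) {
        m <- res$metrics
        ba[cl, sel] <- m$balanced_accuracy
        sens[cl, sel] <- m$sensitivity
        spec[cl, sel] <- m$specificity
        bias[cl, sel] <- m$bias
      }
    }
  }
  structure(list(ba = ba, sensitivity = sens, specificity = spec,
                 bias = bias, cells = cells, stats = stats,
                 config = config),
            class = "eval_grid")
}

#' @export
print.eval_grid <- function(x, digits = 3, ...) {
  cat("LOSO evaluation grid — balanced accuracy\n")
  print(round(x$ba, digits))
  cat("\nColumn means (BA):\n")
  print(round(colMeans(x$ba, na.rm = TRUE), digits))
  invisible(x)
}

#' Summarize an evaluation grid by selection method
#'
#' @param object An `eval_grid`.
#' @param ... Unused.
#' @return Data frame with per-selector mean/sd balanced accuracy and the
#'   best cell.
#' @export
summary.eval_grid <- function(object, ...) {
  sel <- colnames(object$ba)
  out <- data.frame(
    selector = sel,
    mean_ba = colMeans(object$ba, na.rm = TRUE),
    sd_ba = apply(object$ba, 2, sd, na.rm = TRUE),
    best_classifier = rownames(object$ba)[apply(object$ba, 2, which.max)],
    best_ba = apply(object$ba, 2, max, na.rm = TRUE))
  rownames(out) <- NULL
  out
}
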