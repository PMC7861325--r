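test_that("balanced accuracy is the geometric mean with domain checks", {
  expect_equal(balanced_accuracy(0.5, 0.5), 0.5)
  expect_equal(balanced_accuracy(0.9, 0.9), 0.9)  # idempotent on equal args
  expect_error(balanced_accuracy(1.2, 0.5), "\\[0, 1\\]")
  expect_error(balanced_accuracy(0.5, -0.1), "\\[0, 1\\]")
})

test_that("confusion metrics follow their definitions", {
  m <- metrics_from_confusion(tp = 8, fn = 2, tn = 9, fp = 1)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$balanced_accuracy, sqrt(0.72))
  expect_equal(m$bias, -0.1)

  perfect <- metrics_from_confusion(tp = 5, fn = 0, tn = 5, fp = 0)
  expect_equal(unlist(perfect[c("sensitivity", "specificity",
                                "balanced_accuracy", "bias")]),
               c(sensitivity = 1, specificity = 1, balanced_accuracy = 1,
                 bias = 0))

  # all-positive predictor on a balanced test set
  allpos <- metrics_from_confusion(tp = 10, fn = 0, tn = 0, fp = 10)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$balanced_accuracy, 0)
  expect_equal(allpos$bias, 1)

  expect_error(metrics_from_confusion(tp = 0, fn = 0, tn = 5, fp = 0),
               "lacks one class")
})

test_that("undersampling balances to the minority count without replacement", {
  d <- data.frame(subject = 1,
                  label = factor(rep(c("normal", "impaired"), c(153, 80)),
                                 levels = c("normal", "impaired")),
                  x = seq_len(233))
  b <- undersample_balance(d, seed = 1)
  expect_equal(unname(table(b$label)["normal"]), 80)
  expect_equal(unname(table(b$label)["impaired"]), 80)
  expect_false(any(duplicated(b$x)))
  # minority rows untouched
  expect_true(all(d$x[d$label == "impaired"] %in% b$x))

  # already balanced: identity
  bal <- d[c(1:80, 154:233), ]
  expect_equal(undersample_balance(bal, seed = 9)$x, bal$x)

  # different seeds: same counts, possibly different subsets
  b2 <- undersample_balance(d, seed = 2)
  expect_equal(table(b2$label), table(b$label))

  expect_error(undersample_balance(d[d$label == "normal", ]),
               "single class")
})

test_that("classifier contract: determinism, recall and degenerate input", {
  set.seed(7)
  X <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("normal", "impaired"), 30),
              levels = c("normal", "impaired"))
  X[y == "impaired", 1] <- X[y == "impaired", 1] + 3

  for (id in classifier_ids()) {
    m1 <- fit_classifier(id, X, y, seed = 5,
                         params = list(mlp_maxit = 60))
    m2 <- fit_classifier(id, X, y, seed = 5,
                         params = list(mlp_maxit = 60))
    expect_identical(predict_classifier(m1, X), predict_classifier(m2, X),
                     label = paste(id, "determinism"))
    expect_s3_class(m1, "vigileye_model")
  }

  # KNN with k = 1 recalls its training points perfectly
  knn1 <- fit_classifier("KNN", X, y, params = list(knn_k = 1), seed = 1)
  expect_equal(predict_classifier(knn1, X), y, ignore_attr = TRUE)

  # constant-label training data yields a constant predictor
  yc <- factor(rep("normal", 10), levels = c("normal", "impaired"))
  cm <- fit_classifier("LSVM", X[1:10, ], yc)
  expect_true(all(predict_classifier(cm, X) == "normal"))

  # non-finite features are rejected before training
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_classifier("LDA", Xb, y), "non-finite")
})

test_that("QDA separates well-separated Gaussian clouds", {
  set.seed(11)
  n <- 80
  X <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, mean = 4), n, 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("normal", "impaired"), each = n),
              levels = c("normal", "impaired"))
  m <- fit_classifier("QDA", X, y)
  pred <- predict_classifier(m, X)
  tab <- table(pred, y)
  sens <- tab["impaired", "impaired"] / n
  spec <- tab["normal", "normal"] / n
  expect_gt(balanced_accuracy(sens, spec), 0.95)
})

test_that("LOSO evaluation accounts for every row each iteration", {
  d <- make_toy_labeled(n_subjects = 6, rows_per = 10, seed = 3)
  cfg <- eval_config(n_iterations = 3, seed = 2)
  r <- loso_evaluate("KNN", d, config = cfg)
  # each subject is the test subject exactly n_iterations times
  expect_equal(as.vector(table(r$folds$subject)), rep(3L, 6))
  # pooled totals conserve n_iterations x class counts
  expect_equal(r$counts$tp + r$counts$fn, 3 * sum(d$label == "impaired"))
  expect_equal(r$counts$tn + r$counts$fp, 3 * sum(d$label == "normal"))
  expect_equal(nrow(r$folds), 3 * 6)

  # rerun is bit-identical
  expect_identical(loso_evaluate("KNN", d, config = cfg), r)

  # linearly separable features give a perfect linear SVM
  sep <- make_toy_labeled(n_subjects = 6, rows_per = 10, shift = 30,
                          informative = 1, seed = 4)
  expect_equal(loso_evaluate("LSVM", sep, features = feature_names()[1],
                             config = cfg)$metrics$balanced_accuracy, 1.0)

  expect_error(loso_evaluate("KNN", d[d$subject == 1, ], config = cfg),
               ">= 2 subjects")
})

test_that("standardization makes the protocol scale-invariant", {
  d <- make_toy_labeled(n_subjects = 5, rows_per = 8, seed = 6)
  cfg <- eval_config(n_iterations = 2, seed = 3)
  r1 <- loso_evaluate("LDA", d, config = cfg)
  d2 <- d
  fcols <- intersect(feature_names(), names(d2))
  d2[fcols] <- d2[fcols] * 37
  r2 <- loso_evaluate("LDA", d2, config = cfg)
  expect_equal(r1$metrics, r2$metrics, tolerance = 1e-9)
})

test_that("metric averaging mode aggregates per iteration", {
  d <- make_toy_labeled(n_subjects = 5, rows_per = 8, seed = 8)
  r <- loso_evaluate("KNN", d,
                     config = eval_config(n_iterations = 2, seed = 4,
                                          aggregate = "averaged"))
  expect_true(r$metrics$balanced_accuracy >= 0 &&
              r$metrics$balanced_accuracy <= 1)
  expect_equal(length(r$metrics), 8)
})

test_that("the evaluation grid is consistent, complete and reproducible", {
  d <- make_toy_labeled(n_subjects = 6, rows_per = 10, n_features = 10,
                        informative = 1:3, shift = 1.5, seed = 10)
  cfg <- eval_config(n_iterations = 2, seed = 5, max_features = 3,
                     wrapper_mode = "nested",
                     ga = list(population = 6, generations = 3))
  cls <- c("LDA", "KNN", "NBNRM")
  g <- run_grid(d, classifiers = cls, config = cfg)
  expect_equal(dim(g$ba), c(3, 5))
  expect_equal(dim(g$sensitivity), c(3, 5))
  expect_equal(dim(g$specificity), c(3, 5))
  # per-cell internal consistency and the AM-GM bound
  expect_equal(g$ba, sqrt(g$sensitivity * g$specificity), tolerance = 1e-12)
  expect_true(all(g$ba <= (g$sensitivity + g$specificity) / 2 + 1e-12))
  expect_true(all(g$bias == g$sensitivity - g$specificity))
  # bit-identical rerun under the same master seed
  g2 <- run_grid(d, classifiers = cls, config = cfg)
  expect_identical(g$ba, g2$ba)
  s <- summary(g)
  expect_equal(s$selector, colnames(g$ba))
})

test_that("wrapper objectives score subsets by LOSO balanced accuracy", {
  d <- make_toy_labeled(n_subjects = 5, rows_per = 8, n_features = 8,
                        informative = 1:2, shift = 3, seed = 12)
  obj <- wrapper_objective(d, "LDA", eval_config(seed = 6))
  good <- obj(feature_names()[1:2])
  noise <- obj(feature_names()[7:8])
  expect_gt(good, noise)
  expect_equal(obj(character(0)), 0)
})
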