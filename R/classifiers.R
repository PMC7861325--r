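#' The 14 classifier identifiers of the evaluation grid
#'
#' Four support vector machines (linear, quadratic, cubic, Gaussian
#' kernels), linear and quadratic discriminant analysis, k-nearest
#' neighbours, a CART decision tree, four Naive Bayes variants (box,
#' Epanechnikov, normal and triangular kernels) and two multilayer
#' perceptrons (one and two hidden layers).
#'
#' @return Character vector of length 14.
#' @export
classifier_ids <- function() {
  c("LSVM", "QSVM", "CSVM", "GSVM", "LDA", "QDA", "KNN", "TREE",
    "NBBOX", "NBEPA", "NBNRM", "NBTRI", "MLP3", "MLP4")
}

# ---- kernel Naive Bayes (box / Epanechnikov / triangular) -------------
# Class-conditional univariate kernel density estimates per feature,
# Silverman's rule bandwidth, evaluated by interpolation with a small
# density floor; log-posteriors add the training class log-priors.
kernel_nb_fit <- function(X, y, kernel) {
  classes <- levels(y)
  dens <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      v <- Xi[, j]
      bw <- bw.nrd0(v)
      if (!is.finite(bw) || bw <= 0) bw <- 1e-3
      density(v, bw = bw, kernel = kernel, n = 512, cut = 3)
    })
  })
  names(dens) <- classes
  prior <- table(y) / length(y)
  list(dens = dens, prior = prior, classes = classes)
}

kernel_nb_predict <- function(fit, X) {
  floor_d <- 1e-9
  ll <- vapply(fit$classes, function(cl) {
    s <- log(as.numeric(fit$prior[cl]))
    out <- rep(s, nrow(X))
    for (j in seq_len(ncol(X))) {
      d <- fit$dens[[cl]][[j]]
      dv <- approx(d$x, d$y, xout = X[, j], yleft = 0, yright = 0)$y
      out <- out + log(pmax(dv, floor_d))
    }
    out
  }, numeric(nrow(X)))
  if (nrow(X) == 1) ll <- matrix(ll, nrow = 1)
  factor(fit$classes[max.col(ll, ties.method = "first")],
         levels = fit$classes)
}

# ---- two-hidden-layer MLP --------------------------------------------
# Logistic activations throughout, cross-entropy loss with a small L2
# penalty, trained by BFGS with analytic backprop gradients.
mlp2_fit <- function(X, y01, hidden = c(10, 5), maxit = 500,
                     decay = 1e-4) {
  p <- ncol(X); h1 <- hidden[1]; h2 <- hidden[2]
  n_par <- p * h1 + h1 + h1 * h2 + h2 + h2 + 1
  unpack <- function(th) {
    i <- 0
    W1 <- matrix(th[i + seq_len(p * h1)], p, h1); i <- i + p * h1
    b1 <- th[i + seq_len(h1)]; i <- i + h1
    W2 <- matrix(th[i + seq_len(h1 * h2)], h1, h2); i <- i + h1 * h2
    b2 <- th[i + seq_len(h2)]; i <- i + h2
    w3 <- th[i + seq_len(h2)]; i <- i + h2
    b3 <- th[i + 1]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, w3 = w3, b3 = b3)
  }
  sigm <- function(z) 1 / (1 + exp(-z))
  forward <- function(w) {
    Z1 <- sigm(sweep(X %*% w$W1, 2, w$b1, "+"))
    Z2 <- sigm(sweep(Z1 %*% w$W2, 2, w$b2, "+"))
    yh <- sigm(drop(Z2 %*% w$w3) + w$b3)
    list(Z1 = Z1, Z2 = Z2, yh = yh)
  }
  fn <- function(th) {
    w <- unpack(th)
    yh <- pmin(pmax(forward(w)$yh, 1e-10), 1 - 1e-10)
    -mean(y01 * log(yh) + (1 - y01) * log(1 - yh)) + decay * sum(th^2)
  }
  gr <- function(th) {
    w <- unpack(th)
    f <- forward(w)
    n <- nrow(X)
    d3 <- (f$yh - y01) / n                      # n
    dW3 <- drop(crossprod(f$Z2, d3))            # h2
    db3 <- sum(d3)
    d2 <- (d3 %o% w$w3) * f$Z2 * (1 - f$Z2)     # n x h2
    dW2 <- crossprod(f$Z1, d2)
    db2 <- colSums(d2)
    d1 <- (d2 %*% t(w$W2)) * f$Z1 * (1 - f$Z1)  # n x h1
    dW1 <- crossprod(X, d1)
    db1 <- colSums(d1)
    c(as.numeric(dW1), db1, as.numeric(dW2), db2, dW3, db3) + 2 * decay * th
  }
  th0 <- runif(n_par, -0.5, 0.5)
  opt <- optim(th0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-8))
  list(weights = unpack(opt$par), hidden = hidden)
}

mlp2_predict <- function(fit, X) {
  sigm <- function(z) 1 / (1 + exp(-z))
  w <- fit$weights
  Z1 <- sigm(sweep(X %*% w$W1, 2, w$b1, "+"))
  Z2 <- sigm(sweep(Z1 %*% w$W2, 2, w$b2, "+"))
  sigm(drop(Z2 %*% w$w3) + w$b3) > 0.5
}

#' Train one classifier of the grid
#'
#' Fits the requested model to a (standardized) feature matrix and binary
#' factor labels. Hyperparameters follow common defaults — KNN k = 5, CART
#' with Gini splitting grown to purity, SVM cost 1 with the median
#' pairwise-distance kernel-scale heuristic for the Gaussian kernel,
#' Silverman bandwidths for the kernel Naive Bayes variants, MLPs with 10
#' (and 10, 5) logistic hidden units — all overridable via `params`.
#'
#' @param id One of [classifier_ids()].
#' @param X Numeric feature matrix (rows = observations).
#' @param y Factor of labels with exactly two levels.
#' @param params Named list of per-classifier overrides (`knn_k`,
#'   `svm_cost`, `mlp_maxit`, `mlp_size`, `mlp_hidden`, `tree_cp`).
#' @param seed Integer seed for the stochastic fits (MLP initialisation).
#' @return An object of class `vigileye_model`.
#' @export
fit_classifier <- function(id, X, y, params = list(), seed = NULL) {
  id <- match.arg(id, classifier_ids())
  stopifnot(is.factor(y), nlevels(y) == 2)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2) {
    # constant-label training data yields a constant predictor
    return(structure(list(id = id, fit = list(constant = as.character(y[1])),
                          levels = levels(y), seed = seed),
                     class = c("vigileye_constant_model", "vigileye_model")))
  }
  cost <- params$svm_cost %||% 1
  fit <- with_seed(seed, switch(id,
    LSVM = e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE),
    QSVM = e1071::svm(X, y, kernel = "polynomial", degree = 2, coef0 = 1,
                      gamma = 1 / ncol(X), cost = cost, scale = FALSE),
    CSVM = e1071::svm(X, y, kernel = "polynomial", degree = 3, coef0 = 1,
                      gamma = 1 / ncol(X), cost = cost, scale = FALSE),
    GSVM = {
      d <- median(dist(X))
      if (!is.finite(d) || d <= 0) d <- sqrt(ncol(X))
      e1071::svm(X, y, kernel = "radial", gamma = 1 / d^2, cost = cost,
                 scale = FALSE)
    },
    LDA = MASS::lda(X, grouping = y),
    QDA = MASS::qda(X, grouping = y),
    KNN = list(train = X, y = y, k = params$knn_k %||% 5),
    TREE = {
      df <- data.frame(X, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = 2, minbucket = 1,
                     cp = params$tree_cp %||% 0, xval = 0))
    },
    NBNRM = e1071::naiveBayes(X, y),
    NBBOX = kernel_nb_fit(X, y, "rectangular"),
    NBEPA = kernel_nb_fit(X, y, "epanechnikov"),
    NBTRI = kernel_nb_fit(X, y, "triangular"),
    MLP3 = nnet::nnet(X, as.numeric(y) - 1, size = params$mlp_size %||% 10,
                      entropy = TRUE, decay = 1e-4,
                      maxit = params$mlp_maxit %||% 500, trace = FALSE),
    MLP4 = mlp2_fit(X, as.numeric(y) - 1,
                    hidden = params$mlp_hidden %||% c(10, 5),
                    maxit = params$mlp_maxit %||% 500)
  ))
  structure(list(id = id, fit = fit, levels = levels(y), seed = seed),
            class = "vigileye_model")
}

#' Predict hard labels from a trained classifier
#'
#' @param model A [fit_classifier()] result.
#' @param X Numeric feature matrix on the same (standardized) scale as
#'   training.
#' @return Factor of predicted labels with the training levels.
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  lv <- model$levels
  if (inherits(model, "vigileye_constant_model"))
    return(factor(rep(model$fit$constant, nrow(X)), levels = lv))
  out <- switch(model$id,
    LSVM = , QSVM = , CSVM = , GSVM = predict(model$fit, X),
    LDA = , QDA = predict(model$fit, X)$class,
    KNN = with_seed(if (is.null(model$seed)) NULL else model$seed + 1L,
                    class::knn(model$fit$train, X, model$fit$y,
                               k = model$fit$k)),
    TREE = predict(model$fit, data.frame(X, check.names = FALSE),
                   type = "class"),
    NBNRM = predict(model$fit, X),
    NBBOX = , NBEPA = , NBTRI = kernel_nb_predict(model$fit, X),
    MLP3 = factor(lv[(predict(model$fit, X) > 0.5) + 1], levels = lv),
    MLP4 = factor(lv[mlp2_predict(model$fit, X) + 1], levels = lv)
  )
  factor(as.character(out), levels = lv)
}
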