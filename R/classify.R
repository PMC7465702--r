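# Classification: Fisher LDA, quadratic-kernel least-squares SVM,
# weighted-majority ensemble, stratified 10-fold cross-validation,
# within-subject standardization, and the exact-binomial chance bound.

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

check_two_classes <- function(labels) {
  lev <- unique(as.character(labels))
  if (length(lev) != 2)
    stop("classifier: need exactly two classes, got ", length(lev))
  lev
}

order_levels <- function(lev, positive) {
  if (!is.null(positive)) c(positive, setdiff(lev, positive)) else lev
}

#' Fisher linear discriminant analysis
#'
#' `w` is proportional to the pooled-covariance inverse applied to the mean
#' difference; the bias places the boundary midway between the projected
#' class means. A ridge term is added if the pooled covariance is singular.
#'
#' @param features n x d matrix.
#' @param labels Two-class label vector.
#' @param positive Label mapped to positive scores (default: first unique).
#' @param ridge Regularization added when the pooled covariance is not
#'   invertible.
#' @return A `linear_classifier` with `w`, `w0`, `class_labels`.
#' @export
lda_fit <- function(features, labels, positive = NULL, ridge = 1e-8) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  lev <- order_levels(check_two_classes(labels), positive)
  x1 <- x[labels == lev[1], , drop = FALSE]
  x2 <- x[labels == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  pool <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))) /
    (nrow(x) - 2)
  w <- tryCatch(solve(pool, mu1 - mu2),
                error = function(e) {
                  message("lda_fit: pooled covariance ridge-regularized")
                  reg <- max(ridge * mean(diag(pool)), 1e-12)
                  solve(pool + reg * diag(ncol(x)), mu1 - mu2)
                })
  w0 <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, w0 = w0, class_labels = lev),
            class = "linear_classifier")
}

#' Signed LDA score
#' @param model A [lda_fit()] model.
#' @param x Feature vector or n x d matrix.
#' @return Signed score(s); positive maps to `class_labels[1]`.
#' @export
lda_score <- function(model, x) {
  if (is.null(dim(x))) sum(model$w * x) + model$w0
  else as.numeric(as_feature_matrix(x) %*% model$w + model$w0)
}

#' Predict labels with an LDA model
#' @inheritParams lda_score
#' @return Character labels (score 0 maps to the second class).
#' @export
lda_predict <- function(model, x) {
  s <- lda_score(model, x)
  ifelse(s > 0, model$class_labels[1], model$class_labels[2])
}

quad_kernel <- function(a, b) (tcrossprod(a, b) + 1)^2

#' Least-squares SVM with quadratic kernel
#'
#' Solves the least-squares SVM linear system with kernel
#' `(x'y + 1)^2` and regularization `gamma`. If the system is singular the
#' regularization is increased tenfold up to three times.
#'
#' @inheritParams lda_fit
#' @param gamma Regularization constant.
#' @return A `kernel_classifier` with dual coefficients, bias, and the
#'   training points.
#' @export
svm_fit <- function(features, labels, positive = NULL, gamma = 1) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  lev <- order_levels(check_two_classes(labels), positive)
  y <- ifelse(labels == lev[1], 1, -1)
  n <- nrow(x)
  # standardize features: the quadratic kernel squares raw magnitudes and
  # would otherwise dominate the regularization term
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  K <- quad_kernel(xs, xs)
  for (attempt in 0:3) {
    A <- rbind(c(0, rep(1, n)),
               cbind(1, K + diag(n) / gamma))
    sol <- tryCatch(solve(A, c(0, y)), error = function(e) NULL)
    if (!is.null(sol)) {
      return(structure(list(alpha = sol[-1], bias = sol[1], X = xs,
                            center = ctr, scale = scl,
                            gamma = gamma, class_labels = lev),
                       class = "kernel_classifier"))
    }
    if (attempt == 3) stop("svm_fit: singular system after regularization")
    gamma <- gamma / 10 # stronger regularization: larger diag(n)/gamma
    message("svm_fit: regularization increased")
  }
}

#' Signed least-squares SVM score
#' @param model A [svm_fit()] model.
#' @param x Feature vector or matrix.
#' @return Signed score(s); positive maps to `class_labels[1]`.
#' @export
svm_score <- function(model, x) {
  xm <- if (is.null(dim(x))) matrix(x, 1) else as_feature_matrix(x)
  xm <- scale(xm, model$center, model$scale)
  s <- as.numeric(quad_kernel(xm, model$X) %*% model$alpha + model$bias)
  if (is.null(dim(x))) s[1] else s
}

#' Predict labels with an LS-SVM model
#' @inheritParams svm_score
#' @export
svm_predict <- function(model, x) {
  s <- svm_score(model, x)
  ifelse(s > 0, model$class_labels[1], model$class_labels[2])
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class and fixed by `seed`; accuracy is
#' correct/total per fold.
#'
#' @param features n x d matrix.
#' @param labels Two-class labels, n >= k.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param method `"lda"`, `"svm"`, `"ensemble"`, or a list with `fit(x, y)`
#'   and `predict(model, x)` functions.
#' @return A `cv_result` with `fold_accuracies`, `mean_accuracy`, `k`,
#'   `seed`.
#' @export
crossval_accuracy <- function(features, labels, k = 10, seed = 1,
                              method = "lda") {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < k) stop("crossval_accuracy: fewer samples than folds")
  fns <- classifier_functions(method, seed)
  folds <- withr::with_seed(seed, {
    f <- integer(n)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    f
  })
  acc <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    te <- !tr
    if (length(unique(labels[tr])) < 2 || !any(te)) return(NA_real_)
    m <- fns$fit(x[tr, , drop = FALSE], labels[tr])
    mean(fns$predict(m, x[te, , drop = FALSE]) == labels[te])
  }, numeric(1))
  structure(list(fold_accuracies = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 k = k, seed = seed),
            class = "cv_result")
}

classifier_functions <- function(method, seed = 1) {
  if (is.list(method)) return(method)
  switch(method,
    lda = list(fit = function(x, y) lda_fit(x, y),
               predict = lda_predict),
    svm = list(fit = function(x, y) svm_fit(x, y),
               predict = svm_predict),
    ensemble = list(fit = function(x, y) ensemble_fit(x, y, seed = seed),
                    predict = ensemble_predict),
    stop("unknown classifier method: ", method))
}

#' Fit the LDA + SVM weighted-majority ensemble
#'
#' Member voting weights are the normalized cross-validated accuracies of
#' each member on the training set; prediction is the weighted vote over
#' member decisions (ties go to the higher-weight member). An optional
#' feature-union mode stacks the two member scores into a logistic
#' combiner.
#'
#' @inheritParams crossval_accuracy
#' @param feature_union Enable the stacked-score combiner (off by default).
#' @return An `ensemble_model` with `members` and `voting_weights`.
#' @export
ensemble_fit <- function(features, labels, k = 10, seed = 1,
                         feature_union = FALSE) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  k <- max(2, min(k, min(table(labels))))
  lda_m <- lda_fit(x, labels)
  svm_m <- svm_fit(x, labels)
  accs <- c(
    lda = crossval_accuracy(x, labels, k, seed, "lda")$mean_accuracy,
    svm = crossval_accuracy(x, labels, k, seed, "svm")$mean_accuracy
  )
  accs[!is.finite(accs)] <- 0.5 # degenerate folds on very small samples
  w <- if (sum(accs) > 0) accs / sum(accs) else c(lda = 0.5, svm = 0.5)
  combiner <- NULL
  if (feature_union) {
    meta <- cbind(lda = lda_score(lda_m, x), svm = svm_score(svm_m, x))
    y01 <- as.numeric(labels == lda_m$class_labels[1])
    combiner <- stats::glm.fit(cbind(1, meta), y01,
                               family = stats::binomial())$coefficients
  }
  structure(list(members = list(lda = lda_m, svm = svm_m),
                 voting_weights = w, feature_union = feature_union,
                 combiner = combiner,
                 class_labels = lda_m$class_labels),
            class = "ensemble_model")
}

#' Predict with the ensemble
#' @param model An [ensemble_fit()] model.
#' @param x Feature vector or matrix.
#' @return Character label(s).
#' @export
ensemble_predict <- function(model, x) {
  if (model$feature_union && !is.null(model$combiner)) {
    meta <- cbind(1, lda = lda_score(model$members$lda, x),
                  svm = svm_score(model$members$svm, x))
    p <- 1 / (1 + exp(-as.numeric(meta %*% model$combiner)))
    return(ifelse(p > 0.5, model$class_labels[1], model$class_labels[2]))
  }
  pl <- lda_predict(model$members$lda, x)
  ps <- svm_predict(model$members$svm, x)
  w <- model$voting_weights
  vapply(seq_along(pl), function(i) {
    if (pl[i] == ps[i]) return(pl[i])
    if (w[["lda"]] >= w[["svm"]]) pl[i] else ps[i]
  }, character(1))
}

#' Signed ensemble score (weight-fused member scores)
#' @inheritParams ensemble_predict
#' @return Numeric score(s); positive maps to `class_labels[1]`.
#' @export
ensemble_score <- function(model, x) {
  w <- model$voting_weights
  w[["lda"]] * lda_score(model$members$lda, x) +
    w[["svm"]] * svm_score(model$members$svm, x)
}

#' Standardize an accuracy table within subjects
#'
#' Each row (subject) is centered by its mean and scaled by its sample SD,
#' removing between-subject baseline differences before comparing methods.
#' Constant rows become zeros.
#'
#' @param table Numeric matrix or data.frame, subjects x methods (>= 2
#'   columns).
#' @return Matrix of within-subject z-scores.
#' @export
standardize_within <- function(table) {
  x <- as.matrix(table)
  if (ncol(x) < 2) stop("standardize_within: need >= 2 methods per subject")
  t(apply(x, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) {
      message("standardize_within: constant row set to zeros")
      return(rep(0, length(r)))
    }
    (r - mean(r)) / s
  }))
}

#' True chance level (exact binomial upper bound)
#'
#' The (1 - alpha) upper quantile of Binomial(n, 1/n_classes) divided by n,
#' in percent: the accuracy a guesser could reach with probability alpha
#' given finitely many trials.
#'
#' @param n_trials Number of trials (>= 1).
#' @param n_classes Number of classes.
#' @param alpha Significance level in (0, 1).
#' @return Chance-level bound in percent.
#' @export
true_chance_level <- function(n_trials, n_classes = 2, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop("true_chance_level: alpha must be in (0, 1)")
  if (n_trials < 1) stop("true_chance_level: n_trials must be >= 1")
  stats::qbinom(1 - alpha, n_trials, 1 / n_classes) / n_trials * 100
}
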