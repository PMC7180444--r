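# Internal classifier registry. Each entry fits on a training matrix and
# predicts labels for a test matrix. Linear/distance-based classifiers are
# z-scaled inside the fold with training statistics (done by the caller);
# tree ensembles consume raw features.

classifier_names <- function() {
  c("lda", "ridge", "svm_linear", "svm_rbf", "knn15", "random_forest",
    "gradient_boosting")
}

classifier_needs_scaling <- function(name) {
  name %in% c("lda", "ridge", "svm_linear", "svm_rbf", "knn15")
}

# Fit + predict in one step; returns predicted factor labels for x_test.
fit_predict <- function(name, x_train, y_train, x_test, seed = 1L) {
  switch(name,
    lda = predict_lda(x_train, y_train, x_test),
    ridge = predict_ridge(x_train, y_train, x_test, alpha = 1),
    svm_linear = predict_svm(x_train, y_train, x_test, kernel = "linear"),
    svm_rbf = predict_svm(x_train, y_train, x_test, kernel = "radial"),
    knn15 = predict_wknn(x_train, y_train, x_test, k = 15L),
    random_forest = predict_rf(x_train, y_train, x_test, seed = seed),
    gradient_boosting = predict_gb(x_train, y_train, x_test, seed = seed),
    stop("unknown classifier: ", name, call. = FALSE)
  )
}

majority_label <- function(y) {
  tab <- table(y)
  factor(names(tab)[which.max(tab)], levels = levels(y))
}

predict_lda <- function(x_train, y_train, x_test) {
  keep <- apply(x_train, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    return(rep(majority_label(y_train), nrow(x_test)))
  }
  fit <- suppressWarnings(
    MASS::lda(x_train[, keep, drop = FALSE], grouping = y_train)
  )
  predict(fit, x_test[, keep, drop = FALSE])$class
}

# L2-regularized least squares on +/-1 targets, unpenalized intercept;
# classification by the sign of the linear predictor.
predict_ridge <- function(x_train, y_train, x_test, alpha = 1) {
  lev <- levels(y_train)
  t_num <- ifelse(y_train == lev[2], 1, -1)
  xc <- colMeans(x_train)
  yc <- mean(t_num)
  xs <- sweep(x_train, 2L, xc)
  p <- ncol(xs)
  beta <- solve(crossprod(xs) + alpha * diag(p), crossprod(xs, t_num - yc))
  scores <- sweep(x_test, 2L, xc) %*% beta + yc
  factor(ifelse(scores >= 0, lev[2], lev[1]), levels = lev)
}

predict_svm <- function(x_train, y_train, x_test, kernel) {
  gam <- 1 / (ncol(x_train) * max(stats::var(as.vector(x_train)),
                                  .Machine$double.eps))
  fit <- e1071::svm(
    x_train, y_train, kernel = kernel, cost = 1, gamma = gam,
    scale = FALSE
  )
  predict(fit, x_test)
}

# Distance-weighted k nearest neighbors (inverse-distance weights; an
# exact-match neighbor decides the vote on its own).
predict_wknn <- function(x_train, y_train, x_test, k = 15L) {
  k <- min(k, nrow(x_train))
  lev <- levels(y_train)
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), `+`) -
    2 * x_test %*% t(x_train)
  d <- sqrt(pmax(d2, 0))
  pred <- character(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    ord <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    di <- d[i, ord]
    if (any(di == 0)) {
      votes <- tapply(rep(1, sum(di == 0)), y_train[ord][di == 0], sum)
    } else {
      votes <- tapply(1 / di, y_train[ord], sum)
    }
    votes <- votes[!is.na(votes)]
    pred[i] <- names(votes)[which.max(votes)]
  }
  factor(pred, levels = lev)
}

predict_rf <- function(x_train, y_train, x_test, n_trees = 100L, seed = 1L) {
  df <- as.data.frame(x_train)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y_train
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = n_trees,
    seed = seed, num.threads = 1L
  )
  te <- as.data.frame(x_test)
  names(te) <- paste0("f", seq_len(ncol(te)))
  predict(fit, data = te, num.threads = 1L)$predictions
}

# Gradient boosting: 100 fixed-size regression trees on the logistic loss.
predict_gb <- function(x_train, y_train, x_test, n_rounds = 100L,
                       seed = 1L) {
  lev <- levels(y_train)
  colnames(x_train) <- paste0("f", seq_len(ncol(x_train)))
  colnames(x_test) <- colnames(x_train)
  fit <- xgboost::xgboost(
    x_train, y_train, nrounds = n_rounds, max_depth = 3,
    verbosity = 0, nthreads = 1, seed = seed
  )
  prob <- predict(fit, x_test)   # probability of the second level
  factor(ifelse(prob >= 0.5, lev[2], lev[1]), levels = lev)
}
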