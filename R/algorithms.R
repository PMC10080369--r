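# SAMME multi-class AdaBoost over depth-1 rpart stumps. Implemented
# in-package: no installed package offers multiclass adaboost with class
# probabilities. Deterministic given the data (no randomness beyond rpart's
# deterministic splits).

fit_samme <- function(X, y, n_trees = 50) {
  y <- droplevels(y)
  K <- nlevels(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(X, check.names = FALSE)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(
      y ~ ., data = cbind(df, y = y), weights = w,
      method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     minbucket = 1, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    if (alpha <= 0) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_samme <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  K <- length(fit$levels)
  votes <- matrix(0, nrow(df), K, dimnames = list(NULL, fit$levels))
  if (length(fit$stumps) == 0) {
    votes[] <- 1 / K
    return(votes)
  }
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  votes / rowSums(votes)
}

samme_importance <- function(fit, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  for (m in seq_along(fit$stumps)) {
    fr <- fit$stumps[[m]]$frame
    var <- as.character(fr$var[fr$var != "<leaf>"])
    if (length(var) > 0) imp[var[1]] <- imp[var[1]] + fit$alphas[m]
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}
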