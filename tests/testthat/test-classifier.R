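test_that("boosting defaults are depth 1, learning rate 0.1, 300 trees", {
  sep <- separable_features()
  m <- train_intent_model(sep$features, sep$labels, seed = 1)
  expect_equal(m$resolved_hyperparameters,
               list(depth = 1L, learning_rate = 0.1, trees = 300L))
  expect_equal(m$algorithm, "gbm")
})

test_that("training validates its inputs", {
  sep <- separable_features()
  expect_error(train_intent_model(sep$features, rep("assault", 30)),
               "single class")
  expect_error(train_intent_model(sep$features, sep$labels[-1]),
               "length mismatch")
  expect_error(train_intent_model(sep$features, c(sep$labels[-1], "bogus")),
               "outside the intent set")
  bad <- sep$features
  bad[[1]][1] <- 2
  expect_error(train_intent_model(bad, sep$labels), "binary")
})

test_that("perfectly separable features give perfect training accuracy", {
  sep <- separable_features()
  for (alg in c("gbm", "random_forest", "maxent", "adaboost", "knn")) {
    m <- train_intent_model(sep$features, sep$labels, algorithm = alg,
                            seed = 3)
    pred <- predict_intent(m, sep$features)
    expect_equal(as.character(pred$label), sep$labels, info = alg)
  }
})

test_that("probabilities are valid distributions and argmax-consistent", {
  withr::with_seed(11, {
    n <- 80
    feats <- tibble::as_tibble(stats::setNames(
      purrr::map(1:6, ~ rbinom(n, 1, 0.5)), paste0("f", 1:6)))
    labels <- sample(intent_levels(), n, TRUE,
                     prob = c(.1, .5, .1, .1, .2))
  })
  for (alg in c("gbm", "svm", "maxent", "knn")) {
    m <- train_intent_model(feats, labels, algorithm = alg, seed = 7,
                            hyperparameters = if (alg == "gbm")
                              list(trees = 40) else list())
    pred <- predict_intent(m, feats)
    P <- as.matrix(pred[, paste0("p_", intent_levels())])
    expect_true(all(abs(rowSums(P) - 1) < 1e-9), info = alg)
    expect_true(all(P >= 0), info = alg)
    # assigned label attains the maximal probability
    expect_true(all(P[cbind(seq_len(n), match(pred$label, intent_levels()))]
                    >= apply(P, 1, max) - 1e-9), info = alg)
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  withr::with_seed(5, {
    feats <- tibble::as_tibble(stats::setNames(
      purrr::map(1:5, ~ rbinom(60, 1, 0.5)), paste0("f", 1:5)))
    labels <- sample(c("assault", "self_harm", "unknown"), 60, TRUE)
    newx <- tibble::as_tibble(stats::setNames(
      purrr::map(1:5, ~ rbinom(25, 1, 0.5)), paste0("f", 1:5)))
  })
  for (alg in c("gbm", "random_forest", "maxent")) {
    m1 <- train_intent_model(feats, labels, algorithm = alg, seed = 42)
    m2 <- train_intent_model(feats, labels, algorithm = alg, seed = 42)
    expect_equal(predict_intent(m1, newx), predict_intent(m2, newx),
                 info = alg)
  }
})

test_that("exact probability ties break by prevalence then class order", {
  P <- matrix(0.2, nrow = 2, ncol = 5,
              dimnames = list(NULL, intent_levels()))
  # assault most prevalent in training -> uniform row goes to assault
  lab <- firearmintent:::pick_labels(P, intent_levels(),
                                     c(10, 50, 5, 8, 20))
  expect_equal(lab, c("assault", "assault"))
  # all-equal prevalence -> first class in declared order
  lab2 <- firearmintent:::pick_labels(P, intent_levels(), rep(10, 5))
  expect_equal(lab2[1], "accident")
})

test_that("models round-trip through save/load prediction-identically", {
  sep <- separable_features()
  withr::with_seed(13, {
    newx <- sep$features[sample(nrow(sep$features), 100, TRUE), ]
  })
  path <- withr::local_tempfile(fileext = ".rds")
  for (alg in c("gbm", "random_forest")) {
    m <- train_intent_model(sep$features, sep$labels, algorithm = alg,
                            seed = 2)
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict_intent(m2, newx), predict_intent(m, newx),
                 info = alg)
  }

  expect_error(load_model(tempfile()), "not found")

  # incompatible format version refused
  arch <- readRDS(path)
  arch$manifest$format_version <- 999L
  saveRDS(arch, path)
  expect_error(load_model(path), "format version")
})

test_that("feature-space mismatches are refused", {
  sep <- separable_features()
  m <- train_intent_model(sep$features, sep$labels, seed = 1)
  wrong <- sep$features
  names(wrong)[1] <- "renamed"
  expect_error(predict_intent(m, wrong), "feature names")

  rs <- default_ruleset()
  m2 <- train_intent_model(sep$features, sep$labels, seed = 1, ruleset = rs)
  expect_silent(check_model_ruleset(m2, rs))
  other <- new_ruleset(rs[1:5, c("id", "kind", "intent", "clauses")])
  expect_error(check_model_ruleset(m2, other), "different ruleset")
})

test_that("recalibration refits the same spec from scratch", {
  sep <- separable_features()
  m <- train_intent_model(sep$features, sep$labels, seed = 9)
  same <- recalibrate(m, sep$features, sep$labels, seed = 9)
  expect_equal(predict_intent(same, sep$features),
               predict_intent(m, sep$features))
  expect_error(recalibrate(m, sep$features[0, ], character()), "empty")
})

test_that("feature importances behave at the extremes", {
  withr::with_seed(21, {
    n <- 120
    decisive <- rbinom(n, 1, 0.5)
    feats <- tibble::tibble(
      decisive = decisive,
      constant = 0L,
      noise = rbinom(n, 1, 0.5))
    labels <- ifelse(decisive == 1, "self_harm", "assault")
  })
  m <- train_intent_model(feats, labels, seed = 4,
                          hyperparameters = list(trees = 80))
  imp <- feature_importances(m)
  expect_gt(imp$importance[imp$feature == "decisive"], 0.95)
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)

  # permutation importance: label-independent feature stays near zero
  msvm <- train_intent_model(feats, labels, algorithm = "svm", seed = 4)
  pimp <- feature_importances(msvm, features = feats, labels = labels,
                              n_rep = 10, seed = 8)
  expect_true(all(pimp$importance >= 0))
  expect_gt(pimp$importance[pimp$feature == "decisive"],
            pimp$importance[pimp$feature == "noise"] + 0.2)
  expect_lt(pimp$importance[pimp$feature == "noise"], 0.05)
})

test_that("algorithm comparison reports one row per algorithm", {
  sep <- separable_features(8)
  tab <- compare_algorithms(sep$features, sep$labels, sep$features,
                            sep$labels, seed = 1,
                            hyperparameters = list(gbm = list(trees = 60)))
  expect_equal(tab$algorithm, supported_algorithms())
  expect_equal(tab$avg_f, rep(1, 6))
  expect_true(all(tab$auroc == 1))
})

test_that("tidy and glance summarise fitted models", {
  sep <- separable_features()
  m <- train_intent_model(sep$features, sep$labels, seed = 1)
  g <- glance(m)
  expect_equal(g$algorithm, "gbm")
  expect_equal(g$n_train, 30)
  td <- tidy(m)
  expect_named(td, c("feature", "importance"))
  expect_s3_class(plot_feature_importance(m), "ggplot")
})
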