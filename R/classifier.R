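MODEL_FORMAT_VERSION <- 1L

supported_algorithms <- function() {
  c("gbm", "random_forest", "maxent", "svm", "adaboost", "knn")
}

feature_matrix_of <- function(features) {
  features <- tibble::as_tibble(features)
  cols <- setdiff(names(features), "case_id")
  X <- as.matrix(features[, cols])
  storage.mode(X) <- "double"
  if (length(X) > 0 && !all(X %in% c(0, 1))) {
    stop("feature matrix must be binary 0/1", call. = FALSE)
  }
  X
}

#' Train an intent classifier on binary rule features
#'
#' The production algorithm is shallow gradient boosting (`"gbm"`, via
#' xgboost) with the defaults used throughout: maximum tree depth 1,
#' learning rate 0.1, 300 trees, everything else at library defaults. The
#' comparison algorithms — random forest, maximum entropy
#' (multinomial logistic), SVM, SAMME AdaBoost over stumps, and k-nearest
#' neighbours — share this interface. Training is deterministic given
#' `seed` (single-threaded boosting; seeded randomness elsewhere).
#'
#' @param features Tibble from [build_feature_matrix()] (`case_id` plus 0/1
#'   rule columns; `case_id` optional).
#' @param labels Intent labels aligned with rows; at least 2 classes.
#' @param algorithm One of [supported_algorithms()].
#' @param hyperparameters Named list of overrides. For `"gbm"`: `depth`,
#'   `learning_rate`, `trees`. For `"random_forest"`: `trees`. For
#'   `"adaboost"`: `trees`. For `"knn"`: `k`.
#' @param seed Integer seed.
#' @param ruleset Optional `fi_ruleset`; its hash is stored in the model so
#'   a saved model refuses features from a different ruleset.
#' @return An `fi_intent_model`.
#' @export
train_intent_model <- function(features, labels, algorithm = "gbm",
                               hyperparameters = list(), seed = 1L,
                               ruleset = NULL) {
  algorithm <- match.arg(algorithm, supported_algorithms())
  labels <- assert_intents(labels)
  X <- feature_matrix_of(features)
  if (nrow(X) != length(labels)) {
    stop("feature/label length mismatch: ", nrow(X), " vs ", length(labels),
         call. = FALSE)
  }
  if (nrow(X) == 0) stop("empty training data", call. = FALSE)
  observed <- intent_levels()[intent_levels() %in% unique(as.character(labels))]
  if (length(observed) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  y <- factor(as.character(labels), levels = observed)
  hp <- hyperparameters
  feature_names <- colnames(X)

  fit <- withr::with_seed(seed, switch(
    algorithm,
    gbm = {
      params <- list(objective = "multi:softprob",
                     num_class = length(observed),
                     max_depth = as.integer(hp$depth %||% 1L),
                     eta = hp$learning_rate %||% 0.1,
                     nthread = 1, seed = seed)
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = as.integer(hp$trees %||% 300L),
                         verbose = 0)
    },
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = as.integer(hp$trees %||% 500L)),
    maxent = {
      df <- data.frame(X, check.names = FALSE)
      nnet::multinom(y ~ ., data = cbind(df, y = y), trace = FALSE,
                     maxit = 200, MaxNWts = 5000)
    },
    svm = e1071::svm(x = X, y = y, probability = TRUE, kernel = "radial",
                     scale = FALSE),
    adaboost = fit_samme(X, y, n_trees = as.integer(hp$trees %||% 50L)),
    knn = caret::knn3(x = X, y = y, k = as.integer(hp$k %||% 5L))
  ))

  resolved <- switch(algorithm,
    gbm = list(depth = as.integer(hp$depth %||% 1L),
               learning_rate = hp$learning_rate %||% 0.1,
               trees = as.integer(hp$trees %||% 300L)),
    random_forest = list(trees = as.integer(hp$trees %||% 500L)),
    adaboost = list(trees = as.integer(hp$trees %||% 50L)),
    knn = list(k = as.integer(hp$k %||% 5L)),
    hp)
  prevalence <- table(factor(as.character(labels), levels = intent_levels()))
  structure(list(
    algorithm = algorithm,
    hyperparameters = hp,
    resolved_hyperparameters = resolved,
    fit = fit,
    feature_names = feature_names,
    class_order = intent_levels(),
    observed_classes = observed,
    train_prevalence = as.integer(prevalence),
    seed = as.integer(seed),
    ruleset_hash = if (!is.null(ruleset)) ruleset_hash(ruleset)
                   else string_hash(feature_names)
  ), class = "fi_intent_model")
}

raw_prob_matrix <- function(model, X) {
  observed <- model$observed_classes
  P <- switch(
    model$algorithm,
    gbm = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (is.matrix(p)) {
        dimnames(p) <- list(NULL, observed)
        p
      } else {
        matrix(p, nrow = nrow(X), ncol = length(observed), byrow = TRUE,
               dimnames = list(NULL, observed))
      }
    },
    random_forest = predict(model$fit, X, type = "prob"),
    maxent = {
      p <- predict(model$fit, data.frame(X, check.names = FALSE),
                   type = "probs")
      if (is.null(dim(p))) {
        p <- cbind(1 - p, p)
        colnames(p) <- observed
      }
      p
    },
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    adaboost = predict_samme(model$fit, X),
    knn = predict(model$fit, X, type = "prob")
  )
  P <- as.matrix(P)
  full <- matrix(0, nrow(X), length(model$class_order),
                 dimnames = list(NULL, model$class_order))
  full[, colnames(P)] <- P[, colnames(P), drop = FALSE]
  full / pmax(rowSums(full), .Machine$double.eps)
}

# argmax with deterministic tie-breaking: exact probability ties go to the
# class with the larger training prevalence, then to class order
pick_labels <- function(P, class_order, train_prevalence) {
  prev_rank <- order(-train_prevalence, seq_along(class_order))
  tie_rank <- match(seq_along(class_order), prev_rank)
  apply(P, 1, function(p) {
    top <- which(p >= max(p) - 1e-12)
    class_order[top[which.min(tie_rank[top])]]
  })
}

#' Predict intent labels and per-class probabilities
#'
#' The highest-probability intent is assigned; exact probability ties break
#' by descending training-set class prevalence, then by class order.
#'
#' @param model An `fi_intent_model`.
#' @param features Feature tibble with exactly the model's feature columns.
#' @return Tibble: `case_id` (if supplied), `label`, and one probability
#'   column per intent class (`p_accident`, ..., `p_unknown`), rows
#'   summing to 1.
#' @export
predict_intent <- function(model, features) {
  stopifnot(inherits(model, "fi_intent_model"))
  features <- tibble::as_tibble(features)
  cols <- setdiff(names(features), "case_id")
  if (!identical(sort(cols), sort(model$feature_names))) {
    stop("feature names do not match the model's feature space",
         call. = FALSE)
  }
  X <- as.matrix(features[, model$feature_names])
  storage.mode(X) <- "double"
  P <- raw_prob_matrix(model, X)
  label <- pick_labels(P, model$class_order, model$train_prevalence)
  out <- tibble::tibble(label = factor(label, levels = model$class_order))
  probs <- tibble::as_tibble(P)
  names(probs) <- paste0("p_", model$class_order)
  out <- dplyr::bind_cols(out, probs)
  if ("case_id" %in% names(features)) {
    out <- dplyr::bind_cols(features["case_id"], out)
  }
  out
}

#' Save / load a trained intent model
#'
#' A single-file archive holding a manifest (format version, algorithm,
#' hyperparameters, feature names, class order, ruleset hash, seed) plus
#' the serialized fitted state (boosters serialized portably via their raw
#' format). Loading checks the format version and refuses a file whose
#' feature space does not match the accompanying manifest. A loaded model
#' is prediction-identical to the saved one.
#'
#' @param model An `fi_intent_model`.
#' @param path File path.
#' @return `save_model()` the path invisibly; `load_model()` an
#'   `fi_intent_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fi_intent_model"))
  state <- model
  if (model$algorithm == "gbm") {
    state$fit <- xgboost::xgb.save.raw(model$fit)
  }
  archive <- list(
    manifest = list(
      format_version = MODEL_FORMAT_VERSION,
      algorithm = model$algorithm,
      hyperparameters = model$hyperparameters,
      feature_names = model$feature_names,
      class_order = model$class_order,
      ruleset_hash = model$ruleset_hash,
      seed = model$seed),
    state = state)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  archive <- readRDS(path)
  if (!identical(archive$manifest$format_version, MODEL_FORMAT_VERSION)) {
    stop("model file format version ", archive$manifest$format_version,
         " does not match this package's version ", MODEL_FORMAT_VERSION,
         call. = FALSE)
  }
  model <- archive$state
  if (model$algorithm == "gbm") {
    model$fit <- xgboost::xgb.load.raw(model$fit)
  }
  model
}

#' Check a model against a ruleset before applying it
#'
#' @param model An `fi_intent_model`.
#' @param ruleset An `fi_ruleset`.
#' @return `TRUE` invisibly, or an error if the ruleset hash differs.
#' @export
check_model_ruleset <- function(model, ruleset) {
  if (!identical(model$ruleset_hash, ruleset_hash(ruleset))) {
    stop("model was trained under a different ruleset (hash mismatch); ",
         "refusing to predict", call. = FALSE)
  }
  invisible(TRUE)
}

#' Recalibrate a model on local data
#'
#' Fresh training of the same specification (algorithm + hyperparameters +
#' feature space) on a new site's labelled data; no weights carry over.
#'
#' @param model The original `fi_intent_model` (its spec is reused).
#' @param features Local feature tibble (same ruleset).
#' @param labels Local adjudicated labels.
#' @param seed Seed for the fresh training (defaults to the original).
#' @return A new `fi_intent_model`.
#' @export
recalibrate <- function(model, features, labels, seed = model$seed) {
  stopifnot(inherits(model, "fi_intent_model"))
  if (nrow(tibble::as_tibble(features)) == 0) {
    stop("recalibration data is empty", call. = FALSE)
  }
  cols <- setdiff(names(tibble::as_tibble(features)), "case_id")
  if (!identical(sort(cols), sort(model$feature_names))) {
    stop("recalibration features do not match the model's feature space",
         call. = FALSE)
  }
  out <- train_intent_model(features, labels, algorithm = model$algorithm,
                            hyperparameters = model$hyperparameters,
                            seed = seed)
  out$ruleset_hash <- model$ruleset_hash
  out
}

#' Feature importances
#'
#' Tree ensembles report split-based importances normalised to sum to 1
#' (gain for boosting, Gini decrease for random forest, weighted stump
#' usage for AdaBoost); unused features get 0. Other algorithms fall back
#' to permutation importance: the mean drop in accuracy over `n_rep`
#' seeded permutations of each feature column, floored at 0 (which needs
#' `features`/`labels`).
#'
#' @param model An `fi_intent_model`.
#' @param features,labels Data for permutation importance (ignored for tree
#'   ensembles).
#' @param n_rep Permutation repetitions (default 20).
#' @param seed Seed for the permutations (default: the model's seed).
#' @return Tibble `(feature, importance)` sorted by descending importance.
#' @export
feature_importances <- function(model, features = NULL, labels = NULL,
                                n_rep = 20, seed = model$seed) {
  stopifnot(inherits(model, "fi_intent_model"))
  fn <- model$feature_names
  imp <- switch(
    model$algorithm,
    gbm = {
      tab <- xgboost::xgb.importance(model = model$fit)
      v <- stats::setNames(numeric(length(fn)), fn)
      if (!is.null(tab) && nrow(tab) > 0) v[tab$Feature] <- tab$Gain
      v
    },
    random_forest = {
      v <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
      v <- v[fn]
      names(v) <- fn
      v[is.na(v)] <- 0
      if (sum(v) > 0) v / sum(v) else v
    },
    adaboost = samme_importance(model$fit, fn),
    {
      if (is.null(features) || is.null(labels)) {
        stop("permutation importance for algorithm '", model$algorithm,
             "' needs features and labels", call. = FALSE)
      }
      labels <- assert_intents(labels)
      X <- tibble::as_tibble(features)
      base_acc <- mean(as.character(predict_intent(model, X)$label) ==
                         as.character(labels))
      withr::with_seed(seed, {
        drops <- vapply(fn, function(f) {
          accs <- vapply(seq_len(n_rep), function(r) {
            Xp <- X
            Xp[[f]] <- sample(Xp[[f]])
            mean(as.character(predict_intent(model, Xp)$label) ==
                   as.character(labels))
          }, numeric(1))
          base_acc - mean(accs)
        }, numeric(1))
        pmax(drops, 0)
      })
    })
  tibble::tibble(feature = fn, importance = unname(imp[fn])) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
}

#' Compare classification algorithms on a common split
#'
#' Trains every requested algorithm on the same training data and reports
#' unweighted average F-score, macro AUROC and macro AUPRC on the same
#' tuning set (means over classes for which the area is defined).
#'
#' @param train_features,train_labels Training split.
#' @param tune_features,tune_labels Tuning split.
#' @param algorithms Character vector of algorithms.
#' @param seed Shared seed.
#' @param hyperparameters Named list mapping algorithm to its
#'   hyperparameter list (unlisted algorithms use defaults).
#' @return Tibble: one row per algorithm with `avg_f`, `auroc`, `auprc`.
#' @export
compare_algorithms <- function(train_features, train_labels,
                               tune_features, tune_labels,
                               algorithms = supported_algorithms(),
                               seed = 1L, hyperparameters = list()) {
  purrr::map_dfr(algorithms, function(alg) {
    model <- train_intent_model(train_features, train_labels, algorithm = alg,
                                hyperparameters = hyperparameters[[alg]] %||%
                                  list(), seed = seed)
    pred <- predict_intent(model, tune_features)
    cm <- confusion_matrix(pred$label, tune_labels)
    avg_f <- unweighted_average_f(per_class_metrics(cm))
    probs <- as.matrix(pred[, paste0("p_", intent_levels())])
    colnames(probs) <- intent_levels()
    areas <- roc_pr_curves(probs, tune_labels)
    tibble::tibble(algorithm = alg, avg_f = avg_f,
                   auroc = mean(areas$auroc, na.rm = TRUE),
                   auprc = mean(areas$auprc, na.rm = TRUE))
  })
}
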