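#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix into long form
#'
#' @param x An `fi_confusion`.
#' @param ... Unused.
#' @return Tibble: `predicted`, `adjudicated`, `n`.
#' @export
tidy.fi_confusion <- function(x, ...) {
  df <- as.data.frame.table(unclass(x), responseName = "n",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("predicted", "adjudicated")
  tibble::as_tibble(df)
}

#' Tidy an evaluation report
#'
#' @param x An `fi_evaluation`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @export
tidy.fi_evaluation <- function(x, ...) x$metrics

#' @rdname tidy.fi_evaluation
#' @export
glance.fi_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, average_f = x$average_f,
                 accuracy = sum(diag(unclass(x$confusion))) / x$n)
}

#' Tidy a fitted intent model (feature importances)
#'
#' @param x An `fi_intent_model`.
#' @param ... Passed to [feature_importances()] (for permutation-based
#'   algorithms supply `features` and `labels`).
#' @return Tibble `(feature, importance)`.
#' @export
tidy.fi_intent_model <- function(x, ...) feature_importances(x, ...)

#' @rdname tidy.fi_intent_model
#' @export
glance.fi_intent_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_features = length(x$feature_names),
                 n_classes = length(x$observed_classes),
                 n_train = sum(x$train_prevalence),
                 seed = x$seed)
}

#' @export
print.fi_intent_model <- function(x, ...) {
  cat(sprintf("Intent classifier (%s), %d binary rule features, trained on %d cases\n",
              x$algorithm, length(x$feature_names), sum(x$train_prevalence)))
  cat("Classes observed in training:",
      paste(x$observed_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a confusion matrix as a tile heat map
#'
#' @param object An `fi_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fi_confusion <- function(object, ...) {
  df <- tidy.fi_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adjudicated, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(intent_levels())) +
    ggplot2::scale_x_discrete(limits = intent_levels()) +
    ggplot2::labs(x = "Adjudicated intent", y = "Predicted intent",
                  fill = "Cases") +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics of an evaluation
#'
#' @param object An `fi_evaluation`.
#' @param ... Unused.
#' @return A ggplot of per-class precision, recall, specificity, F.
#' @export
autoplot.fi_evaluation <- function(object, ...) {
  df <- object$metrics |>
    dplyr::select("class", "specificity", "precision", "recall", "f_score") |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot feature importances of a fitted model
#'
#' @param model An `fi_intent_model`.
#' @param ... Passed to [feature_importances()].
#' @return A ggplot.
#' @export
plot_feature_importance <- function(model, ...) {
  df <- feature_importances(model, ...)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$importance),
                                   y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Importance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
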