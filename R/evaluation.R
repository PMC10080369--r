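#' Confusion matrix over the five intent classes
#'
#' Rows are predicted intent, columns adjudicated intent, both in fixed
#' class order (accident, assault, legal_intervention, self_harm,
#' unknown) — the same orientation the reporting tables use, so published
#' matrices load directly as fixtures.
#'
#' @param predicted,adjudicated Equal-length label vectors over the
#'   five-class intent set (labels outside it are an error).
#' @return An `fi_confusion`: a 5x5 integer matrix with class dimnames.
#' @export
confusion_matrix <- function(predicted, adjudicated) {
  predicted <- assert_intents(predicted, "predicted")
  adjudicated <- assert_intents(adjudicated, "adjudicated")
  if (length(predicted) != length(adjudicated)) {
    stop("predicted and adjudicated labels differ in length", call. = FALSE)
  }
  m <- table(predicted = predicted, adjudicated = adjudicated)
  m <- matrix(as.integer(m), 5, 5, dimnames = dimnames(m))
  structure(m, class = c("fi_confusion", "matrix", "array"))
}

#' Load / write a confusion matrix as CSV
#'
#' CSV layout: a header row of class names and a leading column of class
#' names; predicted classes in rows, adjudicated in columns.
#'
#' @param path File path.
#' @return `read_confusion_csv()` an `fi_confusion`.
#' @export
read_confusion_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_integer(), class = readr::col_character()),
    progress = FALSE)
  stopifnot(identical(df$class, intent_levels()),
            identical(setdiff(names(df), "class"), intent_levels()))
  m <- as.matrix(df[, intent_levels()])
  rownames(m) <- intent_levels()
  names(dimnames(m)) <- c("predicted", "adjudicated")
  storage.mode(m) <- "integer"
  structure(m, class = c("fi_confusion", "matrix", "array"))
}

#' @rdname read_confusion_csv
#' @param m An `fi_confusion`.
#' @export
write_confusion_csv <- function(m, path) {
  df <- tibble::as_tibble(unclass(m))
  df <- dplyr::bind_cols(tibble::tibble(class = intent_levels()), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Per-class classification metrics from a confusion matrix
#'
#' For class c with the matrix's predicted-row / adjudicated-column
#' orientation: TP = m[c,c], FP = row sum minus TP, FN = column sum minus
#' TP, TN = the rest. Then specificity = TN / (TN + FP), precision =
#' TP / (TP + FP), recall = TP / (TP + FN), F = 2PR / (P + R). All
#' arithmetic is exact on integer counts before any rounding; 0/0 cases
#' are reported as 0, except specificity, which is 1 when no true
#' negatives exist to misclassify (TN + FP = 0).
#'
#' @param m An `fi_confusion`.
#' @return Tibble: `class`, `tp`, `fp`, `fn`, `tn`, `specificity`,
#'   `precision`, `recall`, `f_score`.
#' @export
per_class_metrics <- function(m) {
  stopifnot(inherits(m, "fi_confusion"))
  total <- sum(m)
  purrr::map_dfr(seq_along(intent_levels()), function(i) {
    tp <- m[i, i]
    fp <- sum(m[i, ]) - tp
    fn <- sum(m[, i]) - tp
    tn <- total - tp - fp - fn
    div0 <- function(num, den, zero = 0) if (den == 0) zero else num / den
    precision <- div0(tp, tp + fp)
    recall <- div0(tp, tp + fn)
    f <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(
      class = intent_levels()[i],
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      specificity = div0(tn, tn + fp, zero = 1),
      precision = precision, recall = recall, f_score = f)
  })
}

#' Unweighted average F-score
#'
#' Arithmetic mean of the five per-class F-scores, the headline comparison
#' metric between algorithms and sites.
#'
#' @param metrics Output of [per_class_metrics()].
#' @return A single number.
#' @export
unweighted_average_f <- function(metrics) {
  stopifnot("f_score" %in% names(metrics))
  mean(metrics$f_score)
}

# one-vs-rest ROC/PR areas for a score vector; ties handled by threshold
# grouping (one operating point per distinct score)
binary_areas <- function(scores, truth) {
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0) return(list(auroc = NA_real_, auprc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, if (n_neg == 0) rep(0, length(fp)) else fp / n_neg)
  auroc <- if (n_neg == 0) NA_real_ else
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # step-wise interpolated PR area: sum over thresholds of
  # precision * increase in recall
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

#' One-vs-rest ROC and precision-recall areas
#'
#' For each intent class, the class's predicted probability scores the
#' cases and the adjudicated label defines positives. AUROC is the
#' trapezoid area over the ROC; AUPRC is the step-wise interpolated area
#' (precision times recall increment at each threshold). Tied scores
#' collapse into one operating point. A class absent from the truth gets
#' `NA` areas (undefined, not 0).
#'
#' @param probabilities Numeric matrix (cases x classes) with class-named
#'   columns, rows summing to 1, or a prediction tibble from
#'   [predict_intent()].
#' @param adjudicated Adjudicated labels.
#' @return Tibble: `class`, `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(probabilities, adjudicated) {
  if (is.data.frame(probabilities)) {
    cols <- paste0("p_", intent_levels())
    stopifnot(all(cols %in% names(probabilities)))
    probabilities <- as.matrix(probabilities[, cols])
    colnames(probabilities) <- intent_levels()
  }
  stopifnot(all(intent_levels() %in% colnames(probabilities)))
  adjudicated <- assert_intents(adjudicated, "adjudicated")
  stopifnot(nrow(probabilities) == length(adjudicated))
  if (any(abs(rowSums(probabilities[, intent_levels(), drop = FALSE]) - 1)
          > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  purrr::map_dfr(intent_levels(), function(cls) {
    a <- binary_areas(probabilities[, cls], adjudicated == cls)
    tibble::tibble(class = cls, auroc = a$auroc, auprc = a$auprc)
  })
}

#' Split cases into train / tune / test partitions
#'
#' A uniform random permutation under `seed` followed by contiguous
#' allocation, so realized sizes are within one case of the target
#' fractions; deterministic given the seed. No stratification by default
#' (mirroring designs that freeze splits before labels exist); pass
#' `stratify_by` to balance a label across partitions.
#'
#' @param case_ids Character vector of case ids (non-empty, unique).
#' @param fractions Named or unnamed numeric vector summing to 1; names
#'   default to `train`/`tune`/`test` (or `train`/`test` for length 2).
#' @param seed Integer seed.
#' @param stratify_by Optional vector aligned with `case_ids`; the split is
#'   performed within each stratum.
#' @return Tibble: `case_id`, `split`.
#' @export
split_cases <- function(case_ids, fractions = c(train = 0.6, tune = 0.2,
                                                test = 0.2),
                        seed = 1L, stratify_by = NULL) {
  if (length(case_ids) == 0) stop("no cases to split", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (is.null(names(fractions))) {
    names(fractions) <- if (length(fractions) == 2) c("train", "test")
                        else c("train", "tune", "test")[seq_along(fractions)]
  }
  alloc <- function(ids, rng_offset) {
    n <- length(ids)
    perm <- withr::with_seed(seed + rng_offset, sample(ids))
    sizes <- diff(c(0, round(cumsum(fractions) * n)))
    tibble::tibble(case_id = perm,
                   split = rep(names(fractions), times = sizes))
  }
  if (is.null(stratify_by)) {
    out <- alloc(case_ids, 0L)
  } else {
    strata <- split(case_ids, stratify_by)
    out <- purrr::imap_dfr(strata, function(ids, nm)
      alloc(ids, utf8ToInt(substr(nm, 1, 1))))
  }
  out[match(case_ids, out$case_id), ]
}

#' Compare model-assigned intent with ICD-coded intent
#'
#' Side-by-side per-class metrics for the two coding arms against the same
#' researcher-adjudicated labels, restricted to the identical case set:
#' cases lacking an ICD label are excluded from both arms before any
#' metric is computed.
#'
#' @param icd ICD-coded intent labels (NA where no discharge code exists).
#' @param model_labels Model-assigned labels, aligned.
#' @param adjudicated Adjudicated labels, aligned.
#' @return Tibble of 10 rows (5 classes x 2 arms): `arm`, `class`,
#'   `specificity`, `precision`, `recall`, `f_score`, plus the common
#'   `n_cases` used.
#' @export
compare_to_icd <- function(icd, model_labels, adjudicated) {
  stopifnot(length(icd) == length(model_labels),
            length(icd) == length(adjudicated))
  keep <- !is.na(icd)
  icd <- icd[keep]
  model_labels <- model_labels[keep]
  adjudicated <- adjudicated[keep]
  arms <- list(icd = icd, model = model_labels)
  purrr::imap_dfr(arms, function(labels, arm) {
    met <- per_class_metrics(confusion_matrix(labels, adjudicated))
    tibble::tibble(arm = arm, class = met$class,
                   specificity = met$specificity, precision = met$precision,
                   recall = met$recall, f_score = met$f_score,
                   n_cases = sum(keep))
  })
}

#' Full evaluation report for one model on one test set
#'
#' @param predictions Prediction tibble from [predict_intent()].
#' @param adjudicated Adjudicated labels aligned with `predictions`.
#' @return An `fi_evaluation` list: `$confusion` (fi_confusion),
#'   `$metrics` (per-class metrics joined with per-class areas),
#'   `$average_f`, `$n`.
#' @export
evaluate_predictions <- function(predictions, adjudicated) {
  cm <- confusion_matrix(predictions$label, adjudicated)
  met <- per_class_metrics(cm)
  areas <- roc_pr_curves(predictions, adjudicated)
  met <- dplyr::left_join(met, areas, by = "class")
  structure(list(confusion = cm, metrics = met,
                 average_f = unweighted_average_f(met),
                 n = length(adjudicated)),
            class = "fi_evaluation")
}

#' @export
print.fi_evaluation <- function(x, ...) {
  cat(sprintf("Intent evaluation on %d cases\n", x$n))
  cat(sprintf("Unweighted average F-score: %.2f\n\n",
              round_half_up(x$average_f, 2)))
  df <- x$metrics
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = 2)
  print(as.data.frame(df[, c("class", "specificity", "precision", "recall",
                             "f_score", "auroc", "auprc")]),
        row.names = FALSE)
  invisible(x)
}
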