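test_that("confusion matrices have the published orientation and totals", {
  m <- mds_table4_matrix()
  expect_equal(unname(rowSums(m)), c(28, 300, 3, 19, 31))
  expect_equal(unname(colSums(m)), c(27, 285, 8, 14, 47))
  expect_equal(sum(m), 381)

  e <- evs_table4_matrix()
  expect_equal(unname(rowSums(e)), c(50, 204, 5, 42, 3))
  expect_equal(unname(colSums(e)), c(47, 200, 11, 35, 11))
  expect_equal(sum(e), 304)

  # identical labels give a diagonal matrix; a single case a single count
  lab <- c("assault", "accident", "unknown")
  d <- confusion_matrix(lab, lab)
  expect_true(all(d[upper.tri(d) | lower.tri(d)] == 0))
  s <- confusion_matrix("self_harm", "assault")
  expect_equal(sum(s), 1)
  expect_equal(s["self_harm", "assault"], 1L)

  expect_error(confusion_matrix("homicide", "assault"), "outside the intent")
  expect_error(confusion_matrix(lab, lab[-1]), "length")
})

test_that("metrics from the published matrices match the reported values", {
  met <- per_class_metrics(mds_table4_matrix())
  r2 <- function(x) round_half_up(x, 2)
  row <- function(cls) met[met$class == cls, ]
  expect_equal(r2(row("accident")$precision), 0.75)
  expect_equal(r2(row("accident")$recall), 0.78)
  expect_equal(r2(row("assault")$recall), 0.92)
  expect_equal(r2(row("assault")$specificity), 0.59)
  expect_equal(r2(unweighted_average_f(met)), 0.58)

  mev <- per_class_metrics(evs_table4_matrix())
  roww <- function(cls) mev[mev$class == cls, ]
  expect_equal(r2(roww("accident")$precision), 0.62)
  expect_equal(r2(roww("assault")$recall), 0.89)
  expect_equal(r2(unweighted_average_f(mev)), 0.58)
})

test_that("metric conventions hold at the degenerate corners", {
  # perfect diagonal: everything 1
  d <- confusion_matrix(rep(intent_levels(), 3), rep(intent_levels(), 3))
  md <- per_class_metrics(d)
  expect_true(all(md$precision == 1 & md$recall == 1 &
                    md$f_score == 1 & md$specificity == 1))
  expect_equal(unweighted_average_f(md), 1)

  # class with zero predictions and zero truths: P = R = F = 0, spec = 1
  c2 <- confusion_matrix(rep("assault", 4), rep("assault", 4))
  m2 <- per_class_metrics(c2)
  leg <- m2[m2$class == "legal_intervention", ]
  expect_equal(c(leg$precision, leg$recall, leg$f_score), c(0, 0, 0))
  expect_equal(leg$specificity, 1)
})

test_that("formula identities hold on random matrices", {
  withr::with_seed(77, {
    for (i in 1:200) {
      m <- random_confusion()
      met <- per_class_metrics(m)
      for (j in 1:5) {
        r <- met[j, ]
        expect_equal(r$precision * (r$tp + r$fp), r$tp)
        expect_equal(r$recall * (r$tp + r$fn), r$tp)
        expect_equal(r$specificity * (r$tn + r$fp), r$tn)
        if (r$precision + r$recall > 0) {
          expect_equal(r$f_score, 2 * r$precision * r$recall /
                         (r$precision + r$recall))
        } else {
          expect_equal(r$f_score, 0)
        }
        expect_equal(r$tp + r$fp + r$fn + r$tn, sum(m))
      }
      expect_equal(unweighted_average_f(met), mean(met$f_score))
    }
  })
})

test_that("ROC and PR areas are exact at the analytic corners", {
  # perfectly separating scores
  probs <- matrix(0, 6, 5, dimnames = list(NULL, intent_levels()))
  truth <- c(rep("assault", 3), rep("accident", 3))
  probs[, "assault"] <- c(.9, .8, .7, .2, .1, .05)
  probs[, "accident"] <- 1 - probs[, "assault"]
  areas <- roc_pr_curves(probs, truth)
  expect_equal(areas$auroc[areas$class == "assault"], 1)
  expect_equal(areas$auprc[areas$class == "assault"], 1)

  # constant scores: AUROC 1/2, AUPRC = prevalence
  probs2 <- matrix(0.2, 10, 5, dimnames = list(NULL, intent_levels()))
  truth2 <- c(rep("assault", 3), rep("accident", 7))
  areas2 <- roc_pr_curves(probs2, truth2)
  expect_equal(areas2$auroc[areas2$class == "assault"], 0.5)
  expect_equal(areas2$auprc[areas2$class == "assault"], 0.3)

  # class absent from truth: undefined, not zero
  expect_true(is.na(areas2$auroc[areas2$class == "unknown"]))

  # invalid distributions refused
  bad <- probs2
  bad[1, 1] <- 0.9
  expect_error(roc_pr_curves(bad, truth2), "sum to 1")
})

test_that("areas equal exhaustive-threshold brute force on random fixtures", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      raw <- matrix(stats::runif(n * 5), n, 5)
      # coarse scores to force plenty of ties
      raw <- round(raw, 1)
      P <- raw / rowSums(raw)
      colnames(P) <- intent_levels()
      truth <- sample(intent_levels(), n, TRUE)
      got <- roc_pr_curves(P, truth)
      for (cls in intent_levels()) {
        want <- brute_force_areas(P[, cls], truth == cls)
        expect_equal(got$auroc[got$class == cls], want$auroc, info = cls)
        expect_equal(got$auprc[got$class == cls], want$auprc, info = cls)
      }
    }
  })
})

test_that("splits are exact, deterministic, and unbiased", {
  ids <- sprintf("c%03d", 1:100)
  sp <- split_cases(ids, seed = 4)
  expect_equal(as.integer(table(sp$split)[c("train", "tune", "test")]),
               c(60L, 20L, 20L))
  expect_setequal(sp$case_id, ids)
  expect_identical(sp, split_cases(ids, seed = 4))
  expect_false(identical(sp$split, split_cases(ids, seed = 5)$split))

  two <- split_cases(ids, c(train = 0.6, test = 0.4), seed = 1)
  expect_equal(as.integer(table(two$split)[c("train", "test")]), c(60L, 40L))

  expect_error(split_cases(character()), "no cases")
  expect_error(split_cases(ids, c(0.5, 0.2)), "sum to 1")

  # over many reseeded draws each case lands in train about 60% of the time
  small <- sprintf("s%d", 1:10)
  hits <- rep(0, 10)
  for (s in 1:400) {
    sp <- split_cases(small, seed = s)
    hits <- hits + (sp$split[match(small, sp$case_id)] == "train")
  }
  p_hat <- hits / 400
  expect_true(all(abs(p_hat - 0.6) < 3 * sqrt(0.6 * 0.4 / 400)))
})

test_that("ICD comparison aligns both arms on the identical case set", {
  adj <- c("assault", "assault", "accident", "self_harm", "unknown")
  icd <- c("accident", "assault", "accident", NA, "unknown")
  mod <- c("assault", "assault", "accident", "self_harm", "assault")
  rep <- compare_to_icd(icd, mod, adj)
  expect_equal(nrow(rep), 10)
  expect_equal(unique(rep$n_cases), 4)  # the NA-ICD case is excluded

  # identical labels give identical metric columns
  same <- compare_to_icd(adj, adj, adj)
  expect_equal(same$f_score[same$arm == "icd"],
               same$f_score[same$arm == "model"])
})

test_that("evaluation reports round, tidy, and plot", {
  withr::with_seed(2, {
    pred_lab <- sample(intent_levels(), 40, TRUE)
    adj <- sample(intent_levels(), 40, TRUE)
    raw <- matrix(stats::runif(200), 40, 5)
    P <- raw / rowSums(raw)
  })
  preds <- tibble::tibble(label = pred_lab)
  preds[paste0("p_", intent_levels())] <- as.data.frame(P)
  ev <- evaluate_predictions(preds, adj)
  expect_s3_class(ev$confusion, "fi_confusion")
  expect_equal(ev$n, 40)
  expect_equal(ev$average_f, unweighted_average_f(ev$metrics))
  expect_named(glance(ev), c("n", "average_f", "accuracy"))
  expect_equal(sum(tidy(ev$confusion)$n), 40)
  expect_s3_class(autoplot(ev$confusion), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_output(print(ev), "Unweighted average F-score")

  # confusion CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(ev$confusion, path)
  expect_equal(unclass(read_confusion_csv(path)), unclass(ev$confusion))
})
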