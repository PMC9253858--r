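make_labelled_cohort <- function(n_dead, n_alive) {
  patients <- lapply(seq_len(n_dead + n_alive), function(i) {
    list(patient_id = i,
         events = data.frame(itemid = "drug_001", starttime = 1, endtime = 2,
                             rate = 1, totalamount = 1,
                             stringsAsFactors = FALSE),
         vitals = list(), label = as.integer(i <= n_dead))
  })
  structure(list(patients = patients, config = NULL, ground_truth = NULL),
            class = "icu_cohort")
}

test_that("splits are stratified, exactly sized and deterministic", {
  coh <- make_labelled_cohort(10, 90)
  sp <- split_data(coh, c(0.6, 0.2, 0.2), seed = 4)
  sizes <- vapply(sp, function(s) length(s$patients), 0)
  expect_equal(unname(sizes), c(60, 20, 20))
  death_rate <- function(s) mean(vapply(s$patients, `[[`, 0, "label"))
  for (s in sp) expect_equal(death_rate(s), 0.1, tolerance = 1e-12)
  sp2 <- split_data(coh, c(0.6, 0.2, 0.2), seed = 4)
  expect_identical(lapply(sp, attr, "ids"), lapply(sp2, attr, "ids"))
  # every patient lands in exactly one split
  all_ids <- sort(unname(unlist(lapply(sp, attr, "ids"))))
  expect_equal(all_ids, 1:100)
  expect_error(split_data(coh, c(0.5, 0.2)), "fractions")
  expect_error(split_data(coh, c(0.5, 0.2, 0.2)), "fractions")
})

test_that("stratification keeps each split's death rate within one patient", {
  coh <- make_labelled_cohort(13, 87)
  sp <- split_data(coh, c(0.6, 0.2, 0.2), seed = 11)
  overall <- 0.13
  for (s in sp) {
    n <- length(s$patients)
    n_dead <- sum(vapply(s$patients, `[[`, 0, "label"))
    expect_lte(abs(n_dead - overall * n), 1)
  }
})

test_that("MCC matches its closed form and the Pearson-correlation oracle", {
  perfect <- confusion_counts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                              c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(perfect$TP, 5); expect_equal(perfect$TN, 5)
  expect_equal(mcc(perfect), 1)
  balanced <- structure(list(TP = 1, TN = 1, FP = 1, FN = 1),
                        class = "confusion_counts")
  expect_equal(mcc(balanced), 0)
  withr::with_seed(19, {
    for (r in 1:100) {
      n <- sample(10:60, 1)
      pred <- rbinom(n, 1, 0.5); lab <- rbinom(n, 1, 0.4)
      if (var(pred) == 0 || var(lab) == 0) next
      expect_equal(mcc(confusion_counts(pred, lab)), cor(pred, lab),
                   tolerance = 1e-10)
    }
  })
  # symmetric under swapping both classes
  cc <- confusion_counts(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
  cc_sw <- confusion_counts(1 - c(1, 0, 1, 0, 1), 1 - c(1, 1, 0, 0, 1))
  expect_equal(mcc(cc), mcc(cc_sw), tolerance = 1e-12)
})

test_that("precision and recall follow the confusion counts with 0/0 -> 0", {
  cc <- structure(list(TP = 8, TN = 0, FP = 2, FN = 2),
                  class = "confusion_counts")
  expect_equal(unname(precision_recall(cc)), c(0.8, 0.8))
  all_right <- structure(list(TP = 3, TN = 4, FP = 0, FN = 0),
                         class = "confusion_counts")
  expect_equal(unname(precision_recall(all_right)), c(1, 1))
  none_called <- structure(list(TP = 0, TN = 5, FP = 0, FN = 2),
                           class = "confusion_counts")
  expect_warning(pr <- precision_recall(none_called), "precision")
  expect_equal(unname(pr["precision"]), 0)
})

test_that("ROC is a monotone staircase and AUC equals the rank statistic", {
  # perfect separation
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc(roc), 1)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  withr::with_seed(23, {
    for (r in 1:30) {
      n <- sample(20:80, 1)
      lab <- rbinom(n, 1, 0.4)
      if (sum(lab) == 0 || sum(lab) == n) next
      sc <- round(runif(n), sample(c(1, 2, 7), 1))  # include heavy ties
      a <- auc(roc_curve(sc, lab))
      # Mann-Whitney U with midranks
      rk <- rank(sc)
      u <- sum(rk[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2
      expect_equal(a, u / (sum(lab) * sum(1 - lab)), tolerance = 1e-10)
      expect_true(all(diff(roc_curve(sc, lab)$fpr) >= 0))
      expect_true(all(diff(roc_curve(sc, lab)$tpr) >= 0))
    }
  })
  expect_error(roc_curve(c(0.2, 0.4), c(1, 1)), "positive and one negative")
})

test_that("AUC is invariant to strictly monotone score transforms and cross-checks pROC", {
  withr::with_seed(29, {
    lab <- rbinom(50, 1, 0.3); lab[1] <- 1; lab[2] <- 0
    sc <- rnorm(50)
    a1 <- auc(roc_curve(sc, lab))
    a2 <- auc(roc_curve(exp(sc), lab))
    expect_equal(a1, a2, tolerance = 1e-12)
    a_ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                            direction = "<")))
    expect_equal(a1, a_ref, tolerance = 1e-10)
  })
})

test_that("model evaluation produces a consistent, JSON-round-trippable report", {
  seqs <- small_sequences()
  cfg <- model_config(cell = "lstm", hidden_size = 4, layers = 1, epochs = 2,
                      lr = 0.02, batch_size = 16, horizon = 24, seed = 5)
  mod <- train_classifier(seqs, config = cfg)
  rep <- evaluate_model(mod, seqs)
  with(rep, {
    expect_equal(counts$TP + counts$TN + counts$FP + counts$FN, n)
    expect_gte(mcc, -1); expect_lte(mcc, 1)
    expect_gte(auc, 0); expect_lte(auc, 1)
    expect_equal(accuracy, (counts$TP + counts$TN) / n)
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- read_eval_report(path)
  expect_equal(back$mcc, rep$mcc, tolerance = 1e-15)
  expect_equal(back$auc, rep$auc, tolerance = 1e-15)
  expect_equal(back$roc, rep$roc, tolerance = 1e-15)
  expect_equal(unclass(back$counts), unclass(rep$counts))
  # a constant majority-class predictor scores MCC 0 and recall 0
  lab <- seqs$labels
  const <- confusion_counts(rep(0, length(lab)), lab)
  expect_equal(mcc(const), 0)
  expect_equal(unname(suppressWarnings(precision_recall(const))["recall"]), 0)
  # predictions identical to labels: MCC 1, AUC 1
  ident <- confusion_counts(lab, lab)
  expect_equal(mcc(ident), 1)
  expect_equal(auc(roc_curve(lab, lab)), 1)
})
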