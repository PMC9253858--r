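# Evaluation of binary mortality prediction: stratified data splitting,
# confusion-matrix metrics with death as the positive class (MCC, precision,
# recall), and ROC/AUC by threshold sweep.

#' Stratified train/validation/test split
#'
#' Randomly partitions a cohort, stratified by outcome label so that small
#' splits keep the cohort's death rate (within one patient per stratum);
#' within each stratum sizes follow largest-remainder rounding of the
#' fractions. Deterministic given `seed`.
#'
#' @param cohort an `icu_cohort`.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed integer seed.
#' @return list of three `icu_cohort`s named `train`, `validation`, `test`,
#'   each carrying attribute `ids` (the patient ids drawn).
#' @export
split_data <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be 3 non-negative numbers summing to 1")
  }
  labels <- vapply(cohort$patients, `[[`, 0, "label")
  assign_split <- integer(length(labels))
  with_seed(seed, {
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      sizes <- floor(fractions * n)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1
      }
      bounds <- cumsum(sizes)
      assign_split[idx[seq_len(bounds[1])]] <- 1L
      if (sizes[2] > 0) assign_split[idx[seq(bounds[1] + 1, bounds[2])]] <- 2L
      if (sizes[3] > 0) assign_split[idx[seq(bounds[2] + 1, bounds[3])]] <- 3L
    }
  })
  take <- function(which_split) {
    keep <- assign_split == which_split
    sub <- cohort
    sub$patients <- cohort$patients[keep]
    if (!is.null(cohort$ground_truth$patients)) {
      sub$ground_truth$patients <- cohort$ground_truth$patients[keep]
    }
    attr(sub, "ids") <- vapply(sub$patients, `[[`, 1, "patient_id")
    sub
  }
  list(train = take(1L), validation = take(2L), test = take(3L))
}

#' Confusion counts with death as the positive class
#'
#' @param predicted,labels binary vectors (1 = death).
#' @return object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels),
            all(predicted %in% c(0, 1)), all(labels %in% c(0, 1)))
  structure(list(TP = sum(predicted == 1 & labels == 1),
                 TN = sum(predicted == 0 & labels == 0),
                 FP = sum(predicted == 1 & labels == 0),
                 FN = sum(predicted == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' the Pearson correlation coefficient of two binary variables; 1 when every
#' case is predicted correctly, -1 when every case is predicted wrongly. Any
#' zero factor in the denominator yields 0 (the standard convention).
#'
#' @param counts a [confusion_counts()] object.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.double(counts$TP); tn <- as.double(counts$TN)
  fp <- as.double(counts$FP); fn <- as.double(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision and recall (death = positive class)
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`; a 0/0 yields 0 with a
#' warning.
#'
#' @inheritParams mcc
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  prec <- if (counts$TP + counts$FP == 0) {
    warning("no positive predictions; precision set to 0")
    0
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    warning("no positive labels; recall set to 0")
    0
  } else counts$TP / (counts$TP + counts$FN)
  c(precision = prec, recall = rec)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the unique scores in descending order (cases with `score >=`
#' threshold are called deaths; tied scores enter at one threshold), prepends
#' `(0, 0)` and appends `(1, 1)`.
#'
#' @param scores numeric risk scores (`p(death)`).
#' @param labels binary outcome labels (1 = death).
#' @return data.frame of class `roc_points` with non-decreasing columns
#'   `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stopf("roc_curve needs at least one positive and one negative label")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(s) sum(scores >= s & labels == 0) / n_neg, 0)
  out <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- unique(out)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param roc a [roc_curve()] result.
#' @return scalar AUC in `[0, 1]`; equals the normalised Mann-Whitney U
#'   statistic of the scores.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate a trained model on a labelled test split
#'
#' Runs [forward_sequence()], derives confusion counts (death = positive),
#' and computes MCC, precision, recall, accuracy, the ROC curve and AUC.
#'
#' @param model a trained `risk_model`.
#' @param test_seqs labelled [assemble_event_vectors()] sequences.
#' @return object of class `eval_report`: `counts`, `mcc`, `precision`,
#'   `recall`, `accuracy`, `roc` (data.frame), `auc`, `n`.
#' @export
evaluate_model <- function(model, test_seqs) {
  stopifnot(inherits(test_seqs, "event_sequences"))
  if (dim(test_seqs$x)[1] == 0) stopf("empty test set")
  if (is.null(test_seqs$labels)) stopf("test set must be labelled")
  pred <- forward_sequence(model, test_seqs)
  counts <- confusion_counts(pred$predicted, test_seqs$labels)
  pr <- suppressWarnings(precision_recall(counts))
  roc <- roc_curve(pred$p_death, test_seqs$labels)
  structure(list(counts = counts, mcc = mcc(counts),
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 accuracy = (counts$TP + counts$TN) / length(test_seqs$labels),
                 roc = as.data.frame(roc), auc = auc(roc),
                 n = length(test_seqs$labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation on %d patients: MCC %.4f, precision %.4f, recall %.4f, AUC %.4f\n",
              x$n, x$mcc, x$precision, x$recall, x$auc))
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n",
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' Reports round-trip losslessly through JSON (full numeric precision).
#'
#' @param report an [evaluate_model()] report.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_eval_report` returns the report.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(counts = unclass(report$counts), mcc = report$mcc,
              precision = report$precision, recall = report$recall,
              accuracy = report$accuracy, roc = report$roc, auc = report$auc,
              n = report$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  if (!file.exists(path)) stopf("evaluation report artifact missing: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(counts = structure(as.list(obj$counts),
                                    class = "confusion_counts"),
                 mcc = obj$mcc, precision = obj$precision,
                 recall = obj$recall, accuracy = obj$accuracy,
                 roc = as.data.frame(obj$roc), auc = obj$auc, n = obj$n),
            class = "eval_report")
}
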