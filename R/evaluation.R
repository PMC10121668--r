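# Repeated-split cross-validation and the AUC / TSS metric machinery,
# including MAX_TSS threshold optimization and the five-band categorical
# scales used to grade model skill.

#' Stratified repeated random splits
#'
#' Each repetition is an independent stratified 80/20 (by default) random
#' split; stratification keeps the presence/background proportions of
#' train and test within one row per class, which prevents foldwise class
#' collapse at small n. Splits are described only as "random" in most SDM
#' protocols; stratification is this package's explicit choice.
#'
#' @param n_rows Number of table rows (>= 5).
#' @param train_fraction Fraction in the calibration side, default 0.8.
#' @param n_rep Number of repetitions, default 10.
#' @param seed Integer seed.
#' @param stratify_by Response labels (0/1 vector of length `n_rows`).
#' @return List of `cv_split` objects: `repetition`, `train_indices`,
#'   `test_indices`.
#' @export
make_splits <- function(n_rows, train_fraction = 0.8, n_rep = 10, seed = 1,
                        stratify_by = NULL) {
  stopifnot(n_rows >= 5, train_fraction > 0, train_fraction < 1, n_rep >= 1)
  strata <- stratify_by %||% rep(1L, n_rows)
  stopifnot(length(strata) == n_rows)
  if (any(table(strata) < 2))
    stop_ensdm("make_splits: every class needs at least 2 rows",
               class = "ensdm_validation_error")
  with_seed(seed, lapply(seq_len(n_rep), function(rep) {
    train <- integer(0)
    for (g in unique(strata)) {
      idx <- which(strata == g)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    structure(list(repetition = rep, train_indices = train,
                   test_indices = setdiff(seq_len(n_rows), train)),
              class = "cv_split")
  }))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability a random presence outranks a random background point, with
#' ties counted 0.5.
#'
#' @param predictions Numeric score vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_ensdm("auc: both classes must be present",
               class = "ensdm_validation_error")
  r <- rank(predictions)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a threshold
#'
#' A row is predicted present iff its score is `>=` the threshold (so
#' threshold 0 predicts everything present).
#'
#' @param threshold Cutoff in `[0, 1]`.
#' @inheritParams auc
#' @return Named vector `c(sensitivity=, specificity=)`.
#' @export
confusion_at <- function(threshold, predictions, labels) {
  pred_pos <- predictions >= threshold
  tp <- sum(pred_pos & labels == 1)
  fn <- sum(!pred_pos & labels == 1)
  tn <- sum(!pred_pos & labels == 0)
  fp <- sum(pred_pos & labels == 0)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' True skill statistic at a threshold
#'
#' `TSS = sensitivity + specificity - 1`, in `[-1, 1]`.
#'
#' @inheritParams confusion_at
#' @return TSS value.
#' @export
tss <- function(predictions, labels, threshold) {
  cm <- confusion_at(threshold, predictions, labels)
  unname(cm["sensitivity"] + cm["specificity"] - 1)
}

#' MAX_TSS threshold
#'
#' Exact maximization of the (step-function) TSS over thresholds: TSS is
#' evaluated at 0, 1, and every midpoint between consecutive sorted unique
#' prediction values; ties are broken toward the smallest threshold.
#'
#' @inheritParams auc
#' @return Named vector `c(threshold=, tss=)`.
#' @export
max_tss_threshold <- function(predictions, labels) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop_ensdm("max_tss_threshold: both classes must be present",
               class = "ensdm_validation_error")
  u <- sort(unique(predictions))
  cand <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                        1)))
  vals <- vapply(cand, function(t) tss(predictions, labels, t), numeric(1))
  best <- which.max(vals)  # which.max takes the first (smallest) maximizer
  c(threshold = cand[best], tss = vals[best])
}

#' Five-band AUC categorization
#'
#' `<= 0.6` invalid; `(0.6, 0.7]` bad; `(0.7, 0.8]` acceptable;
#' `(0.8, 0.9]` good; `> 0.9` excellent.
#'
#' @param value AUC in `[0, 1]`.
#' @return Category label.
#' @export
band_auc <- function(value) {
  stopifnot(value >= 0, value <= 1)
  if (value <= 0.6) "invalid"
  else if (value <= 0.7) "bad"
  else if (value <= 0.8) "acceptable"
  else if (value <= 0.9) "good"
  else "excellent"
}

#' Five-band TSS categorization
#'
#' `<= 0.2` lacking; `(0.2, 0.4]` bad; `(0.4, 0.6]` acceptable;
#' `(0.6, 0.8]` good; `> 0.8` excellent.
#'
#' @param value TSS in `[-1, 1]`.
#' @return Category label.
#' @export
band_tss <- function(value) {
  stopifnot(value >= -1, value <= 1)
  if (value <= 0.2) "lacking"
  else if (value <= 0.4) "bad"
  else if (value <= 0.6) "acceptable"
  else if (value <= 0.8) "good"
  else "excellent"
}

#' Cross-validate one learner family
#'
#' For each split: fit on the calibration rows, score the held-out rows,
#' and record AUC plus the MAX_TSS threshold and its TSS (both measured on
#' the held-out predictions). Folds whose test side lost a class are
#' skipped with a warning.
#'
#' @param spec A [learner_spec()].
#' @param table Training table.
#' @param splits List from [make_splits()].
#' @return Object of class `model_runs`: list with `runs` (each a
#'   `model_run` holding the fitted model and its `eval_metrics`),
#'   `summary` (one data-frame row per kept fold) and `means`.
#' @export
cross_validate <- function(spec, table, splits) {
  runs <- list()
  for (sp in splits) {
    test_y <- table$response[sp$test_indices]
    if (sum(test_y == 1) == 0 || sum(test_y == 0) == 0) {
      warning(sprintf("cross_validate(%s): repetition %d skipped (test ",
                      spec$family, sp$repetition),
              "fold lost a class)", call. = FALSE)
      next
    }
    fold_spec <- learner_spec(spec$family, spec$hyperparameters,
                              seed = derive_seed(spec$seed, sp$repetition))
    model <- fit(fold_spec, table[sp$train_indices, , drop = FALSE])
    p <- predict_table(model, table[sp$test_indices, , drop = FALSE])
    a <- auc(p, test_y)
    mt <- max_tss_threshold(p, test_y)
    cm <- confusion_at(mt["threshold"], p, test_y)
    metrics <- list(auc = a, tss = unname(mt["tss"]),
                    sensitivity = unname(cm["sensitivity"]),
                    specificity = unname(cm["specificity"]),
                    threshold = unname(mt["threshold"]),
                    auc_band = band_auc(a), tss_band = band_tss(mt["tss"]))
    runs[[length(runs) + 1]] <- structure(
      list(spec = fold_spec, repetition = sp$repetition, model = model,
           metrics = metrics),
      class = "model_run")
  }
  if (!length(runs))
    stop_ensdm("cross_validate: every fold was skipped",
               class = "ensdm_validation_error")
  summary <- do.call(rbind, lapply(runs, function(r)
    data.frame(family = r$spec$family, repetition = r$repetition,
               auc = r$metrics$auc, tss = r$metrics$tss,
               threshold = r$metrics$threshold,
               auc_band = r$metrics$auc_band,
               tss_band = r$metrics$tss_band)))
  structure(list(runs = runs, summary = summary,
                 means = c(auc = mean(summary$auc), tss = mean(summary$tss),
                           threshold = mean(summary$threshold))),
            class = "model_runs")
}

#' @export
print.model_runs <- function(x, ...) {
  cat(sprintf("<model_runs %s> %d fold(s): mean AUC %.3f (%s), mean TSS %.3f (%s)\n",
              x$summary$family[1], nrow(x$summary), x$means["auc"],
              band_auc(x$means["auc"]), x$means["tss"],
              band_tss(max(min(x$means["tss"], 1), -1))))
  invisible(x)
}
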