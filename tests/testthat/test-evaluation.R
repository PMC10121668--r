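test_that("splits are stratified, sized, and seed-stable", {
  y <- rep(c(1L, 0L), each = 5)
  sp <- make_splits(10, 0.8, 4, seed = 3, stratify_by = y)
  expect_length(sp, 4)
  for (s in sp) {
    expect_length(s$train_indices, 8)
    expect_length(s$test_indices, 2)
    expect_setequal(c(s$train_indices, s$test_indices), 1:10)
    expect_equal(sum(y[s$test_indices] == 1), 1)
    expect_equal(sum(y[s$test_indices] == 0), 1)
  }
  sp2 <- make_splits(10, 0.8, 4, seed = 3, stratify_by = y)
  expect_identical(sp, sp2)
  expect_error(make_splits(10, 0.8, 2, stratify_by = c(rep(0L, 9), 1L)),
               class = "ensdm_validation_error")
})

test_that("AUC matches the brute-force pairwise oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    labels <- sample(c(0, 1), n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    pred <- round(runif(n), sample(c(1, 2, 16), 1))  # induce ties sometimes
    expect_equal(auc(pred, labels), auc_bruteforce(pred, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc(runif(4), rep(1, 4)), class = "ensdm_validation_error")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(19)
  pred <- runif(40); labels <- sample(c(0, 1), 40, TRUE)
  labels[1:2] <- c(0, 1)
  a <- auc(pred, labels)
  expect_equal(auc(plogis(5 * pred - 2), labels), a, tolerance = 1e-12)
  expect_equal(auc(pred^3, labels), a, tolerance = 1e-12)
})

test_that("confusion and TSS follow the >= threshold convention", {
  pred <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  cm <- confusion_at(0.5, pred, labels)
  expect_equal(unname(cm), c(2 / 3, 1))
  expect_equal(tss(pred, labels, 0.5), 2 / 3, tolerance = 1e-12)

  expect_equal(unname(confusion_at(0, pred, labels)["sensitivity"]), 1)
  high <- confusion_at(0.95, pred, labels)
  expect_equal(unname(high), c(0, 1))
  expect_equal(tss(pred, labels, 0), 0)
  # boundary counts as presence
  expect_equal(unname(confusion_at(0.4, pred, labels)["sensitivity"]), 1)
})

test_that("TSS is identically sensitivity + specificity - 1", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    pred <- runif(n); labels <- sample(c(0, 1), n, TRUE)
    labels[1:2] <- c(0, 1)
    t <- runif(1)
    cm <- confusion_at(t, pred, labels)
    expect_identical(tss(pred, labels, t),
                     unname(cm["sensitivity"] + cm["specificity"] - 1))
  }
})

test_that("MAX_TSS maximization is exact and tie-breaks low", {
  pred <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  mt <- max_tss_threshold(pred, labels)
  expect_equal(unname(mt["tss"]), 1)
  expect_equal(unname(mt["threshold"]), 0.35)  # smallest midpoint with TSS 1

  flat <- max_tss_threshold(rep(0.7, 8), rep(c(1, 0), 4))
  expect_equal(unname(flat), c(0, 0))

  set.seed(29)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    pred <- runif(n); labels <- sample(c(0, 1), n, TRUE)
    labels[1:2] <- c(0, 1)
    mt <- max_tss_threshold(pred, labels)
    expect_equal(unname(mt["tss"]), max_tss_gridscan(pred, labels),
                 tolerance = 1e-12)
    # achieved max is at least the TSS at any fixed threshold
    expect_gte(mt["tss"], tss(pred, labels, 0.5) - 1e-12)
  }
})

test_that("AUC and TSS bands match their published breakpoints and partition the domain", {
  expect_equal(band_auc(0.870), "good")
  expect_equal(band_auc(0.696), "bad")
  expect_equal(band_auc(0.6), "invalid")
  expect_equal(band_auc(0.95), "excellent")
  expect_equal(band_tss(0.673), "good")
  expect_equal(band_tss(0.413), "acceptable")
  expect_equal(band_tss(0.2), "lacking")
  # no gaps or overlaps on a fine grid
  for (v in seq(0, 1, by = 1e-3))
    expect_length(band_auc(v), 1)
  tss_bands <- vapply(seq(-1, 1, by = 1e-3), band_tss, character(1))
  expect_setequal(unique(tss_bands),
                  c("lacking", "bad", "acceptable", "good", "excellent"))
})

test_that("cross-validation is deterministic and recovers a strong signal", {
  sys <- make_signal_table(8, n_layers = 3, n_pres = 80, n_bg = 80, n = 32)
  sp <- make_splits(nrow(sys$table), 0.8, 3, seed = 2,
                    stratify_by = sys$table$response)
  cv1 <- cross_validate(learner_spec("GLM", seed = 4), sys$table, sp)
  cv2 <- cross_validate(learner_spec("GLM", seed = 4), sys$table, sp)
  expect_identical(cv1$summary, cv2$summary)
  expect_equal(nrow(cv1$summary), 3)
  expect_true(all(c("auc", "tss", "threshold") %in% names(cv1$summary)))

  mean_auc <- mean(sapply(1:5, function(s) {
    sys <- make_signal_table(s, n_layers = 3, n_pres = 100, n_bg = 100,
                             n = 48)
    sp <- make_splits(nrow(sys$table), 0.8, 10, seed = s,
                      stratify_by = sys$table$response)
    cross_validate(learner_spec("GLM", seed = s), sys$table, sp)$means["auc"]
  }))
  expect_gt(mean_auc, 0.9)
})

test_that("label-shuffled data yields near-zero mean TSS", {
  # held-out max-TSS equals the two-sample Kolmogorov-Smirnov distance, a
  # statistic with positive O(1/sqrt(n)) bias under the null, so this
  # no-skill check needs large test folds (200 per class) for the bias to
  # sit well inside the band
  tss_null <- sapply(1:20, function(s) {
    sys <- make_signal_table(s, n_layers = 3, n_pres = 1000, n_bg = 1000,
                             n = 64)
    tab <- sys$table
    set.seed(s + 500)
    tab$response <- sample(tab$response)
    sp <- make_splits(nrow(tab), 0.8, 1, seed = s,
                      stratify_by = tab$response)
    cross_validate(learner_spec("GLM", seed = s), tab, sp)$means["tss"]
  })
  expect_lt(abs(mean(tss_null)), 0.15)
})
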