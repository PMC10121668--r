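toy_table <- function(n = 40, seed = 2) {
  set.seed(seed)
  x <- c(runif(n / 2, 1, 4), runif(n / 2, -4, -1))
  df <- data.frame(x = x, response = rep(c(1L, 0L), each = n / 2))
  attr(df, "predictors") <- "x"
  df
}

test_that("a separable toy problem is fit perfectly by GLM", {
  tab <- toy_table()
  m <- fit(learner_spec("GLM"), tab)
  p <- predict_table(m, tab)
  expect_equal(as.integer(p >= 0.5), tab$response)
})

test_that("every family obeys the probability contract on real-ish data", {
  sys <- make_signal_table(3, n_layers = 4, n_pres = 80, n_bg = 80, n = 32)
  tab <- sys$table
  for (fam in all_families()) {
    m <- fit(learner_spec(fam, seed = 5), tab)
    p <- predict_table(m, tab)
    expect_length(p, nrow(tab))
    expect_true(all(is.finite(p)), info = fam)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    # permuting rows permutes predictions identically
    perm <- sample(nrow(tab))
    expect_equal(predict_table(m, tab[perm, ]), p[perm],
                 tolerance = 1e-12, info = fam)
  }
})

test_that("stochastic families are reproducible for a fixed seed", {
  sys <- make_signal_table(6, n_layers = 3, n_pres = 60, n_bg = 60, n = 32)
  for (fam in c("RF", "GBM", "ANN")) {
    p1 <- predict_table(fit(learner_spec(fam, seed = 11), sys$table),
                        sys$table)
    p2 <- predict_table(fit(learner_spec(fam, seed = 11), sys$table),
                        sys$table)
    expect_identical(p1, p2, info = fam)
  }
})

test_that("fit validates its inputs", {
  tab <- toy_table()
  bad <- tab; bad$response <- 1L
  expect_error(fit(learner_spec("GLM"), bad),
               class = "ensdm_validation_error")
  degen <- data.frame(x = rep(1, 10), response = rep(c(0L, 1L), 5))
  attr(degen, "predictors") <- "x"
  expect_error(fit(learner_spec("GLM"), degen), class = "ensdm_fit_error")
  expect_error(learner_spec("SVM"), class = "ensdm_validation_error")
})

test_that("the surface range envelope is the presence-quantile box", {
  set.seed(4)
  df <- data.frame(x = c(seq(2, 8, length.out = 10), runif(10, 0, 10)),
                   response = rep(c(1L, 0L), each = 10))
  attr(df, "predictors") <- "x"
  m <- sre_fit(df, quantile = 0)
  p <- function(v) predict_table(m, data.frame(x = v))
  expect_equal(p(5), 1)
  expect_equal(p(9), 0)
  expect_equal(p(2), 1)    # boundary inclusive
  expect_true(all(predict_table(m, df) %in% c(0, 1)))

  # envelope bounds equal a direct empirical-quantile computation
  set.seed(9)
  df2 <- data.frame(a = rnorm(80), b = runif(80),
                    response = rep(c(1L, 0L), each = 40))
  attr(df2, "predictors") <- c("a", "b")
  m2 <- sre_fit(df2, quantile = 0.025)
  pres <- df2[df2$response == 1, ]
  expect_equal(m2$state$lower,
               c(quantile(pres$a, 0.025, names = FALSE),
                 quantile(pres$b, 0.025, names = FALSE)),
               ignore_attr = TRUE)
  expect_equal(m2$state$upper,
               c(quantile(pres$a, 0.975, names = FALSE),
                 quantile(pres$b, 0.975, names = FALSE)),
               ignore_attr = TRUE)

  # larger quantile never widens the predicted range
  m3 <- sre_fit(df2, quantile = 0.4)
  expect_true(all(predict_table(m3, df2) <= predict_table(m2, df2)))
})

test_that("stack projection agrees with table prediction and keeps the mask", {
  st <- make_small_stack(seed = 10, n = 16)
  v <- st$layers$env1$values; v[1, 1:4] <- NA
  st <- assemble_stack(list(raster_grid(v, name = "env1"),
                            st$layers$env2, st$layers$env3))
  tm <- gen_true_suitability(st, truth_spec(list(env1 = 2)))
  occ <- sample_presences(tm, 40, seed = 1)
  bg <- sample_background(st, occ, seed = 2)
  tab <- extract_table(st, occ, bg)
  m <- fit(learner_spec("GLM"), tab)
  smap <- predict_stack(m, st)
  expect_identical(smap$probability$mask, stack_mask(st))
  expect_equal(smap$probability$values[occ$points],
               predict_table(m, tab[seq_len(40), ]), tolerance = 1e-9)

  const <- assemble_stack(lapply(names(st$layers), function(nm)
    raster_grid(matrix(1, 8, 8), name = nm)))
  cmap <- predict_stack(m, const)
  expect_equal(max(cmap$probability$values) - min(cmap$probability$values), 0)

  expect_error(predict_stack(m, assemble_stack(list(
    raster_grid(matrix(0, 8, 8), name = "other")))),
    class = "ensdm_validation_error")
})

test_that("scale-free families ignore constant shifts of a predictor", {
  sys <- make_signal_table(12, n_layers = 3, n_pres = 60, n_bg = 60, n = 32)
  tab <- sys$table
  shifted <- tab
  shifted$env1 <- shifted$env1 + 100
  for (fam in c("RF", "CTA", "GBM")) {
    m <- fit(learner_spec(fam, seed = 3), tab)
    ms <- fit(learner_spec(fam, seed = 3),
              `attr<-`(shifted, "predictors", attr(tab, "predictors")))
    expect_equal(predict_table(ms, shifted), predict_table(m, tab),
                 tolerance = 1e-9, info = fam)
  }
  for (fam in c("GLM", "GAM", "ANN", "MAXENT")) {
    m <- fit(learner_spec(fam, seed = 3),
             `attr<-`(shifted, "predictors", attr(tab, "predictors")))
    expect_true(all(is.finite(predict_table(m, shifted))), info = fam)
  }
})

test_that("all probabilistic families reach good holdout AUC on a two-variable niche; SRE reaches acceptable", {
  # two-layer strong-signal system; SRE is a binary-output envelope whose
  # AUC is (sens+spec)/2 and therefore sits structurally lower
  aucs <- sapply(all_families(), function(fam) {
    mean(sapply(1:5, function(s) {
      sys <- make_signal_table(s, n_layers = 2)
      sp <- make_splits(nrow(sys$table), 0.8, 1, seed = s,
                        stratify_by = sys$table$response)
      cross_validate(learner_spec(fam, seed = s), sys$table,
                     sp)$means["auc"]
    }))
  })
  for (fam in setdiff(all_families(), "SRE"))
    expect_gte(aucs[[fam]], 0.75)
  expect_gte(aucs[["SRE"]], 0.65)
})
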