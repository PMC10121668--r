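fake_run <- function(tss, family = "GLM", model = NULL, rep = 1) {
  structure(list(spec = learner_spec(family),
                 repetition = rep, model = model,
                 metrics = list(tss = tss, auc = NA_real_,
                                threshold = 0.5)),
            class = "model_run")
}

test_that("ensemble membership and weights follow the TSS keep rule", {
  ens <- build_ensemble(list(fake_run(0.9), fake_run(0.85), fake_run(0.5)),
                        tss_cutoff = 0.8)
  expect_length(ens$members, 2)
  expect_false(ens$fallback_used)
  expect_equal(ens$weights, c(0.9, 0.85) / 1.75)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-9)

  single <- build_ensemble(list(fake_run(0.7)), tss_cutoff = 0.5)
  expect_equal(single$weights, 1)
})

test_that("an unreachable cutoff triggers the logged fallback", {
  runs <- list(fake_run(0.673), fake_run(0.53), fake_run(0.413))
  expect_message(ens <- build_ensemble(runs, tss_cutoff = 0.8),
                 "falling back")
  expect_true(ens$fallback_used)
  expect_length(ens$members, 3)
  expect_equal(ens$weights, c(0.673, 0.53, 0.413) / sum(c(0.673, 0.53,
                                                          0.413)))
  expect_error(suppressMessages(build_ensemble(list(fake_run(0),
                                                    fake_run(-0.2)))),
               class = "ensdm_validation_error")
})

test_that("ensemble prediction is a cellwise convex combination", {
  st <- make_small_stack(seed = 14, n = 16)
  tm <- gen_true_suitability(st, truth_spec(list(env1 = 2)))
  occ <- sample_presences(tm, 40, seed = 1)
  bg <- sample_background(st, occ, seed = 2)
  tab <- extract_table(st, occ, bg)
  sp <- make_splits(nrow(tab), 0.8, 2, seed = 3, stratify_by = tab$response)
  runs <- c(cross_validate(learner_spec("GLM", seed = 1), tab, sp)$runs,
            cross_validate(learner_spec("RF", seed = 1), tab, sp)$runs)
  ens <- suppressMessages(build_ensemble(runs, tss_cutoff = 0))
  maps <- lapply(ens$members, function(m) predict_stack(m$model, st))
  emap <- ensemble_predict(ens, st)
  lo <- Reduce(pmin, lapply(maps, function(m) m$probability$values))
  hi <- Reduce(pmax, lapply(maps, function(m) m$probability$values))
  ok <- !stack_mask(st)
  expect_true(all(emap$probability$values[ok] >= lo[ok] - 1e-12))
  expect_true(all(emap$probability$values[ok] <= hi[ok] + 1e-12))

  solo <- build_ensemble(list(ens$members[[1]]), tss_cutoff = 0)
  expect_equal(ensemble_predict(solo, st)$probability$values,
               maps[[1]]$probability$values)
  # table and stack routes agree
  expect_equal(ensemble_predict(ens, tab)[seq_len(40)],
               ensemble_predict(ens, st)$probability$values[occ$points],
               tolerance = 1e-9)
})

test_that("ensembling does not degrade below the best member", {
  deltas <- sapply(1:5, function(s) {
    sys <- make_signal_table(s, n_layers = 4, n_pres = 100, n_bg = 100,
                             n = 48)
    tab <- sys$table
    sp <- make_splits(nrow(tab), 0.8, 1, seed = s,
                      stratify_by = tab$response)
    runs <- unlist(lapply(c("GLM", "RF", "GAM"), function(f)
      cross_validate(learner_spec(f, seed = s), tab, sp)$runs),
      recursive = FALSE)
    ens <- suppressMessages(build_ensemble(runs, tss_cutoff = 0.8))
    ti <- sp[[1]]$test_indices
    member_auc <- vapply(runs, function(r)
      auc(predict_table(r$model, tab[ti, ]), tab$response[ti]), numeric(1))
    auc(ensemble_predict(ens, tab[ti, ]), tab$response[ti]) - max(member_auc)
  })
  expect_gte(mean(deltas), -0.05)
})

test_that("suitability classes use the published closed/open boundaries", {
  p <- matrix(c(0.8, 0.2, 0.19999, 0.4, 0.6, 0.79999, 0.39999, 0.59999,
                0, 1, 0.5, 0.999), 3, 4)
  map <- suitability_map(raster_grid(p), "test")
  cls <- classify_suitability(map)
  labels <- attr(cls, "labels")
  got <- labels[cls$values]
  want <- c("excellent", "low", "unsuitable", "moderate", "high", "high",
            "low", "moderate", "unsuitable", "excellent", "moderate",
            "excellent")
  expect_equal(got, want)
  # every probability maps to exactly one class
  grid <- seq(0, 1, by = 1e-3)
  cls2 <- classify_suitability(
    suitability_map(raster_grid(matrix(grid, ncol = 1)), "g"))
  expect_true(all(cls2$values %in% 1:5))
})

test_that("class areas partition the study area", {
  p <- matrix(rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 20), 10, 10)
  cls <- classify_suitability(suitability_map(raster_grid(p), "t"))
  sm <- class_area_summary(cls)
  expect_equal(sm$percent, rep(20, 5))
  expect_equal(sum(sm$percent), 100, tolerance = 0.01)
  expect_equal(sum(sm$area_km2), 100)

  u <- classify_suitability(suitability_map(raster_grid(matrix(0.5, 5, 5)),
                                            "t"))
  su <- class_area_summary(u)
  expect_equal(su$percent[su$class == "moderate"], 100)
  expect_equal(sum(su$percent[su$class != "moderate"]), 0)
})

test_that("response curves span the data and respect monotone models", {
  tab <- make_signal_table(16, n_layers = 2, n_pres = 60, n_bg = 60,
                           n = 32)$table
  m <- fit(learner_spec("GLM"), tab)
  rc <- response_curve(m, tab, "env1", n_points = 50)
  expect_equal(nrow(rc), 50)
  expect_equal(rc$value[1], min(tab$env1))
  expect_equal(rc$value[50], max(tab$env1))
  expect_true(all(rc$response >= 0 & rc$response <= 1))
  sign_env1 <- sign(coef(m$state$model)[2])  # slope of the env1 term
  diffs <- diff(rc$response) * sign_env1
  expect_true(all(diffs >= -1e-12))

  # a model that ignores the varied predictor gives a flat curve
  tab0 <- tab
  tab0$env2 <- NULL
  attr(tab0, "predictors") <- "env1"
  m1 <- fit(learner_spec("GLM"), tab0)
  rc_flat <- response_curve(m1, tab, "env2")
  expect_lt(max(rc_flat$response) - min(rc_flat$response), 1e-9)
  expect_error(response_curve(m, tab, "nope"),
               class = "ensdm_validation_error")
})
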