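# Ten base-learner families behind one fit/predict-probability contract.
# The families are the classic ensemble-SDM set: GLM, GAM, GBM, RF, CTA,
# ANN, FDA, MARS, a MaxEnt-style penalized presence/background logistic,
# and a surface range envelope (SRE). Each family is implemented with the
# standard statistical equivalent available in R; hyperparameters are
# fixed, documented defaults so runs are reproducible.

LEARNER_FAMILIES <- c("GLM", "GBM", "RF", "SRE", "CTA", "ANN", "FDA",
                      "MARS", "GAM", "MAXENT")

#' Learner specification
#'
#' @param family One of GLM, GBM, RF, SRE, CTA, ANN, FDA, MARS, GAM,
#'   MAXENT.
#' @param hyperparameters Named list overriding the family defaults
#'   (see Details).
#' @param seed Integer seed; stochastic families (RF, GBM, ANN and the
#'   penalized fits) are deterministic for a fixed seed.
#'
#' @details Family defaults: RF 500 trees; GBM 1000 boosting rounds,
#'   learning rate 0.01, depth 3; ANN one hidden layer of 8 units, weight
#'   decay 0.05, 300 iterations on standardized inputs; GAM per-variable
#'   thin-plate smooths with basis dimension 4; MARS/FDA a fixed-knot
#'   hinge basis (knots at the 1/3 and 2/3 quantiles) with lasso term
#'   selection (lambda 0.01) or linear discriminant analysis on the kept
#'   basis; MAXENT ridge logistic (lambda 0.01) on standardized linear +
#'   quadratic features; SRE presence-quantile envelope at quantile 0.025.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(family, hyperparameters = list(), seed = 1) {
  family <- toupper(family)
  if (!family %in% LEARNER_FAMILIES)
    stop_ensdm("learner_spec: unknown family '", family, "'; registered: ",
               paste(LEARNER_FAMILIES, collapse = ", "),
               class = "ensdm_validation_error")
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

hyper <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

check_training_table <- function(table) {
  if (!"response" %in% names(table))
    stop_ensdm("fit: table has no `response` column",
               class = "ensdm_validation_error")
  y <- table$response
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop_ensdm("fit: need at least one presence and one background row",
               class = "ensdm_validation_error")
  invisible(TRUE)
}

clamp01 <- function(p) pmin(1, pmax(0, as.numeric(p)))

# -- shared feature machinery ------------------------------------------

standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}
apply_standardizer <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$s, "/")

# Fixed-knot hinge (piecewise-linear) basis shared by MARS and FDA.
hinge_knots <- function(x, probs = c(1 / 3, 2 / 3)) {
  apply(x, 2, stats::quantile, probs = probs, names = FALSE)
}
hinge_expand <- function(x, knots) {
  cols <- lapply(seq_len(ncol(x)), function(j) {
    ks <- knots[, j]
    cbind(x[, j],
          do.call(cbind, lapply(ks, function(k) pmax(x[, j] - k, 0))),
          do.call(cbind, lapply(ks, function(k) pmax(k - x[, j], 0))))
  })
  b <- do.call(cbind, cols)
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  b
}

# -- fit ----------------------------------------------------------------

#' Fit one learner family on a training table
#'
#' @param spec A [learner_spec()].
#' @param table Training table from [extract_table()].
#' @return An object of class `sdm_model` with fields `spec`, `state`,
#'   `variables`. Predictions from [predict_table()]/[predict_stack()]
#'   are probabilities in `[0, 1]` (SRE: exactly `{0, 1}`).
#' @export
fit <- function(spec, table) {
  stopifnot(inherits(spec, "learner_spec"))
  check_training_table(table)
  vars <- predictor_names(table)
  x <- as.matrix(table[, vars, drop = FALSE])
  y <- as.integer(table$response)
  if (spec$family != "SRE" && nrow(unique(x)) < 2)
    stop_ensdm("fit: degenerate table (a single unique predictor row); ",
               spec$family, " requires predictor variance",
               class = "ensdm_fit_error")
  state <- with_seed(spec$seed,
    switch(spec$family,
      GLM = fit_glm(x, y, spec),
      GAM = fit_gam(x, y, spec),
      GBM = fit_gbm(x, y, spec),
      RF = fit_rf(x, y, spec),
      CTA = fit_cta(x, y, spec),
      ANN = fit_ann(x, y, spec),
      MARS = fit_mars(x, y, spec),
      FDA = fit_fda(x, y, spec),
      MAXENT = fit_maxent(x, y, spec),
      SRE = fit_sre(x, y, spec)))
  structure(list(spec = spec, state = state, variables = vars),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model %s> variables: %s\n", x$spec$family,
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

fit_glm <- function(x, y, spec) {
  d <- data.frame(x, .y = y, check.names = FALSE)
  f <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(x)),
                                             collapse = " + ")))
  m <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = d))
  list(model = m)
}

fit_gam <- function(x, y, spec) {
  k <- hyper(spec, "k", 4)
  d <- data.frame(x, .y = y, check.names = FALSE)
  terms <- vapply(colnames(x), function(nm) {
    nu <- length(unique(x[, nm]))
    if (nu > k + 1) sprintf("s(`%s`, k = %d)", nm, k)
    else sprintf("`%s`", nm)
  }, character(1))
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- suppressWarnings(
    mgcv::gam(f, family = stats::binomial(), data = d, method = "REML"))
  list(model = m)
}

fit_gbm <- function(x, y, spec) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = hyper(spec, "depth", 3),
                  eta = hyper(spec, "learning_rate", 0.01),
                  nthread = 1, seed = spec$seed),
    data = dm, nrounds = hyper(spec, "n_trees", 1000), verbose = 0)
  list(model = m)
}

fit_rf <- function(x, y, spec) {
  m <- randomForest::randomForest(x = as.data.frame(x),
                                  y = factor(y, levels = c(0, 1)),
                                  ntree = hyper(spec, "n_trees", 500))
  list(model = m)
}

fit_cta <- function(x, y, spec) {
  d <- data.frame(x, .y = factor(y, levels = c(0, 1)), check.names = FALSE)
  f <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(x)),
                                             collapse = " + ")))
  m <- rpart::rpart(f, data = d, method = "class",
                    control = rpart::rpart.control(
                      minsplit = hyper(spec, "minsplit", 10),
                      cp = hyper(spec, "cp", 0.01)))
  list(model = m)
}

fit_ann <- function(x, y, spec) {
  st <- standardizer(x)
  z <- apply_standardizer(x, st)
  m <- nnet::nnet(z, y, size = hyper(spec, "size", 8),
                  decay = hyper(spec, "decay", 0.05),
                  maxit = hyper(spec, "maxit", 300),
                  entropy = TRUE, trace = FALSE)
  list(model = m, st = st)
}

fit_mars <- function(x, y, spec) {
  knots <- hinge_knots(x)
  b <- hinge_expand(x, knots)
  keep <- apply(b, 2, stats::sd) > 1e-10
  m <- glmnet::glmnet(b[, keep, drop = FALSE], y, family = "binomial",
                      alpha = 1)
  list(model = m, knots = knots, keep = keep,
       lambda = hyper(spec, "lambda", 0.01))
}

fit_fda <- function(x, y, spec) {
  knots <- hinge_knots(x)
  b <- hinge_expand(x, knots)
  g <- factor(y, levels = c(0, 1))
  within_sd <- pmin(apply(b[y == 0, , drop = FALSE], 2, stats::sd),
                    apply(b[y == 1, , drop = FALSE], 2, stats::sd))
  keep <- is.finite(within_sd) & within_sd > 1e-8
  if (!any(keep))
    stop_ensdm("fit: FDA basis degenerate on this table",
               class = "ensdm_fit_error")
  m <- suppressWarnings(MASS::lda(b[, keep, drop = FALSE], grouping = g))
  list(model = m, knots = knots, keep = keep)
}

fit_maxent <- function(x, y, spec) {
  st <- standardizer(x)
  z <- apply_standardizer(x, st)
  feats <- cbind(z, z^2)
  colnames(feats) <- c(colnames(x), paste0(colnames(x), "_sq"))
  m <- glmnet::glmnet(feats, y, family = "binomial", alpha = 0)
  list(model = m, st = st, lambda = hyper(spec, "lambda", 0.01))
}

fit_sre <- function(x, y, spec) {
  q <- hyper(spec, "quantile", 0.025)
  if (q < 0 || q >= 0.5)
    stop_ensdm("fit: SRE quantile must be in [0, 0.5)",
               class = "ensdm_validation_error")
  pres <- x[y == 1, , drop = FALSE]
  if (nrow(pres) < 1)
    stop_ensdm("fit: SRE needs at least one presence row",
               class = "ensdm_fit_error")
  lower <- apply(pres, 2, stats::quantile, probs = q, names = FALSE)
  upper <- apply(pres, 2, stats::quantile, probs = 1 - q, names = FALSE)
  list(lower = lower, upper = upper, quantile = q)
}

#' Fit a surface range envelope directly
#'
#' The SRE (bioclim-style) classifier stores, per predictor, the
#' `[q, 1 - q]` empirical quantile interval of the presence rows only and
#' predicts presence (1) iff every predictor falls inside its interval.
#'
#' @param table Training table (only presence rows shape the envelope).
#' @param quantile Tail fraction trimmed from each side, in `[0, 0.5)`.
#' @param seed Unused (SRE is deterministic); kept for contract symmetry.
#' @return An `sdm_model` of family SRE.
#' @export
sre_fit <- function(table, quantile = 0.025, seed = 1) {
  fit(learner_spec("SRE", list(quantile = quantile), seed = seed), table)
}

# -- predict ------------------------------------------------------------

#' Predict occurrence probability for table rows
#'
#' @param model An `sdm_model`.
#' @param table Data frame containing the model's predictor columns.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_table <- function(model, table) {
  stopifnot(inherits(model, "sdm_model"))
  missing <- setdiff(model$variables, names(table))
  if (length(missing))
    stop_ensdm("predict_table: missing column(s): ",
               paste(missing, collapse = ", "),
               class = "ensdm_validation_error")
  x <- as.matrix(table[, model$variables, drop = FALSE])
  predict_matrix(model, x)
}

predict_matrix <- function(model, x) {
  s <- model$state
  p <- switch(model$spec$family,
    GLM = stats::predict(s$model,
                         newdata = as.data.frame(x), type = "response"),
    GAM = as.numeric(stats::predict(s$model, newdata = as.data.frame(x),
                                    type = "response")),
    GBM = stats::predict(s$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    RF = stats::predict(s$model, newdata = as.data.frame(x),
                        type = "prob")[, "1"],
    CTA = stats::predict(s$model, newdata = as.data.frame(x),
                         type = "prob")[, "1"],
    ANN = as.numeric(stats::predict(s$model, apply_standardizer(x, s$st))),
    MARS = {
      b <- hinge_expand(x, s$knots)
      as.numeric(stats::predict(s$model, b[, s$keep, drop = FALSE],
                                s = s$lambda, type = "response"))
    },
    FDA = {
      b <- hinge_expand(x, s$knots)
      stats::predict(s$model, b[, s$keep, drop = FALSE])$posterior[, "1"]
    },
    MAXENT = {
      z <- apply_standardizer(x, s$st)
      feats <- cbind(z, z^2)
      as.numeric(stats::predict(s$model, feats, s = s$lambda,
                                type = "response"))
    },
    SRE = {
      inside <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x)))
        inside <- inside & x[, j] >= s$lower[j] & x[, j] <= s$upper[j]
      as.numeric(inside)
    })
  unname(clamp01(p))
}

#' Project a fitted model onto a raster stack
#'
#' @param model An `sdm_model`.
#' @param stack An `env_stack` containing the model's predictor layers.
#' @return A [suitability_map()]; masked cells stay masked.
#' @export
predict_stack <- function(model, stack) {
  stopifnot(inherits(model, "sdm_model"))
  missing <- setdiff(model$variables, layer_names(stack))
  if (length(missing))
    stop_ensdm("predict_stack: stack '", stack$label, "' missing layer(s): ",
               paste(missing, collapse = ", "),
               class = "ensdm_validation_error")
  msk <- stack_mask(stack)
  idx <- which(!msk)
  x <- vapply(model$variables, function(nm) stack$layers[[nm]]$values[idx],
              numeric(length(idx)))
  if (length(idx) == 1) x <- matrix(x, nrow = 1,
                                    dimnames = list(NULL, model$variables))
  p <- predict_matrix(model, x)
  out <- matrix(NA_real_, nrow(msk), ncol(msk))
  out[idx] <- p
  suitability_map(raster_grid(out, msk, stack$cell_size_km,
                              paste0("suitability_", model$spec$family)),
                  source = model$spec$family)
}
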