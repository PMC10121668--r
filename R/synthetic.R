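# Synthetic study systems: spatially autocorrelated predictor stacks, a
# known logistic truth, presence sampling proportional to suitability, and
# future scenarios as additive/multiplicative perturbations. These are the
# study conditions every simulation-based test runs under.

#' Layer specification for the synthetic generator
#'
#' @param name Layer name.
#' @param mean,sd Target mean and standard deviation of the generated
#'   field (layer units).
#' @param radius Smoothing radius in cells; the field is white noise
#'   convolved with a uniform (box) kernel of half-width `radius`, which
#'   produces the broad spatial gradients real climate layers show.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(name, mean = 0, sd = 1, radius = 3) {
  stopifnot(radius >= 0, sd >= 0)
  list(name = as.character(name), mean = mean, sd = sd,
       radius = as.integer(radius))
}

# Box-kernel smoothing with edge renormalisation (the kernel is clipped at
# the grid edge and re-weighted so edges are not biased toward zero).
box_smooth <- function(m, radius) {
  if (radius == 0) return(m)
  ones <- matrix(1, nrow(m), ncol(m))
  num <- box_sum(m, radius)
  den <- box_sum(ones, radius)
  num / den
}

# Exact windowed sum via padded cumulative sums (separable box filter).
box_sum <- function(m, radius) {
  sum_1d <- function(mat, r) {
    n <- nrow(mat)
    cs <- rbind(0, apply(mat, 2, cumsum))
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r, 0)
    cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  t(sum_1d(t(sum_1d(m, radius)), radius))
}

#' Generate a synthetic environmental stack
#'
#' Each base layer is white Gaussian noise smoothed with a uniform kernel
#' of the requested radius, then affinely rescaled to the requested mean
#' and sd. Collinear copies are built as `source + N(0, noise_sd)`, which
#' guarantees a high empirical correlation with the source whenever
#' `noise_sd` is small relative to `sd(source)` (|r| > 0.8 for
#' `noise_sd <= 0.25 * sd(source)` in expectation).
#'
#' @param n_rows,n_cols Grid dimensions (each at least 8).
#' @param layer_specs List of [layer_spec()] entries.
#' @param collinear_pairs List of `list(source=, copy_name=, noise_sd=)`.
#' @param seed Integer seed; fixed seed gives a bit-identical stack.
#' @param mask Optional logical nodata matrix applied to every layer.
#' @param cell_size_km Cell size, default 1 km (the resolution the
#'   pipeline's area accounting assumes by default).
#' @param label Stack label.
#' @return An `env_stack`.
#' @export
gen_env_stack <- function(n_rows, n_cols, layer_specs,
                          collinear_pairs = list(), seed = 1,
                          mask = NULL, cell_size_km = 1,
                          label = "current") {
  if (n_rows < 8 || n_cols < 8)
    stop_ensdm("gen_env_stack: grid must be at least 8 x 8",
               class = "ensdm_validation_error")
  grids <- with_seed(seed, {
    base <- lapply(layer_specs, function(sp) {
      z <- box_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                      sp$radius)
      z <- (z - mean(z)) / stats::sd(z) * sp$sd + sp$mean
      raster_grid(z, mask, cell_size_km, sp$name)
    })
    names(base) <- vapply(layer_specs, `[[`, character(1), "name")
    copies <- lapply(collinear_pairs, function(cp) {
      src <- base[[cp$source]]
      if (is.null(src))
        stop_ensdm("gen_env_stack: unknown source layer '", cp$source,
                   "' in collinear_pairs", class = "ensdm_validation_error")
      z <- src$values + matrix(stats::rnorm(n_rows * n_cols, sd = cp$noise_sd),
                               n_rows, n_cols)
      raster_grid(z, mask, cell_size_km, cp$copy_name)
    })
    c(base, copies)
  })
  assemble_stack(grids, label)
}

#' Known truth for parameter-recovery simulations
#'
#' A logistic "true niche": `p = plogis(intercept + sum coef_l * z_l +
#' sum quad_l * z_l^2)` where `z_l` is the layer standardized by its
#' non-masked mean and sd. The optional quadratic terms allow a thermal
#' optimum (a unimodal response), without which a uniform warming scenario
#' could only erode — never create — suitable habitat.
#'
#' @param coefficients Named list/vector of linear weights by layer name
#'   (all-zero weights are allowed and give a flat p = 0.5 surface).
#' @param intercept Scalar intercept on the logit scale.
#' @param quadratic Optional named list/vector of quadratic weights.
#' @return A `truth_spec`.
#' @export
truth_spec <- function(coefficients, intercept = 0, quadratic = list()) {
  coefficients <- as.list(coefficients)
  quadratic <- as.list(quadratic)
  if (!length(coefficients) && !length(quadratic))
    stop_ensdm("truth_spec: at least one coefficient required",
               class = "ensdm_validation_error")
  structure(list(coefficients = coefficients, intercept = intercept,
                 quadratic = quadratic, link = "logistic"),
            class = "truth_spec")
}

#' Evaluate the true suitability surface of a synthetic system
#'
#' @param stack An `env_stack` containing every layer the truth names.
#' @param truth A [truth_spec()].
#' @return A [suitability_map()] with source `"truth"`.
#' @export
gen_true_suitability <- function(stack, truth) {
  stopifnot(inherits(truth, "truth_spec"))
  need <- union(names(truth$coefficients), names(truth$quadratic))
  missing <- setdiff(need, layer_names(stack))
  if (length(missing))
    stop_ensdm("gen_true_suitability: layer(s) not in stack: ",
               paste(missing, collapse = ", "),
               class = "ensdm_validation_error")
  msk <- stack_mask(stack)
  eta <- matrix(truth$intercept, nrow(msk), ncol(msk))
  zcache <- list()
  std <- function(nm) {
    if (is.null(zcache[[nm]])) {
      v <- stack$layers[[nm]]$values
      mu <- mean(v[!msk]); s <- stats::sd(v[!msk])
      if (!is.finite(s) || s == 0) s <- 1
      zcache[[nm]] <<- (v - mu) / s
    }
    zcache[[nm]]
  }
  for (nm in names(truth$coefficients))
    eta <- eta + truth$coefficients[[nm]] * std(nm)
  for (nm in names(truth$quadratic))
    eta <- eta + truth$quadratic[[nm]] * std(nm)^2
  p <- stats::plogis(eta)
  p[msk] <- NA_real_
  suitability_map(raster_grid(p, msk, stack$cell_size_km, "truth"),
                  source = "truth")
}

#' Sample presence cells proportional to true suitability
#'
#' Cells are drawn without replacement with probability proportional to
#' the truth surface, the simplest generative model consistent with
#' presence-only data (no observation-error layer).
#'
#' @param truth_map A [suitability_map()].
#' @param n_target Number of presences requested; the realized count is
#'   `min(n_target, #cells with p > 0)`.
#' @param seed Integer seed.
#' @return An [occurrence_set()] with label `"presence"`.
#' @export
sample_presences <- function(truth_map, n_target, seed = 1) {
  stopifnot(inherits(truth_map, "suitability_map"), n_target >= 1)
  g <- truth_map$probability
  idx <- which(!g$mask & g$values > 0)
  if (!length(idx))
    stop_ensdm("sample_presences: truth map has no cell with p > 0",
               class = "ensdm_validation_error")
  n <- min(n_target, length(idx))
  take <- with_seed(seed,
    sample(idx, n, replace = FALSE, prob = g$values[idx]))
  occurrence_set(cbind(row = (take - 1L) %% nrow(g$values) + 1L,
                       col = (take - 1L) %/% nrow(g$values) + 1L),
                 label = "presence")
}

#' Future-climate scenario as a perturbation of the base stack
#'
#' @param label Scenario identifier (e.g. `"GCM1-SSP370-2050"`).
#' @param deltas Named additive shifts (layer units), e.g. a warming of
#'   `+2.76` on an annual-mean-temperature layer.
#' @param scale_factors Named multiplicative factors.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(label, deltas = list(), scale_factors = list()) {
  structure(list(label = as.character(label), deltas = as.list(deltas),
                 scale_factors = as.list(scale_factors)),
            class = "scenario_spec")
}

#' Apply a scenario to a stack
#'
#' Each named layer becomes `layer * scale + delta`; shape and mask are
#' unchanged and the stack label is taken from the scenario.
#'
#' @param stack An `env_stack`.
#' @param scenario A [scenario_spec()].
#' @return A new `env_stack`.
#' @export
apply_scenario <- function(stack, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  unknown <- setdiff(union(names(scenario$deltas),
                           names(scenario$scale_factors)),
                     layer_names(stack))
  if (length(unknown))
    stop_ensdm("apply_scenario: unknown layer(s): ",
               paste(unknown, collapse = ", "),
               class = "ensdm_validation_error")
  grids <- lapply(stack$layers, function(g) {
    v <- g$values
    sc <- scenario$scale_factors[[g$name]]
    de <- scenario$deltas[[g$name]]
    if (!is.null(sc)) v <- v * sc
    if (!is.null(de)) v <- v + de
    raster_grid(v, g$mask, g$cell_size_km, g$name)
  })
  assemble_stack(grids, scenario$label)
}
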