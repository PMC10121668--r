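# TSS-weighted ensembling, suitability classification, and response
# curves.

#' Build a TSS-weighted ensemble from cross-validated runs
#'
#' Runs with held-out TSS at or above `tss_cutoff` become members; their
#' weights are proportional to TSS (clamped below at 0) and normalized to
#' sum to 1. If no run reaches the cutoff the ensemble falls back to
#' keeping every run, still TSS-weighted, and flags `fallback_used` — a
#' deliberate resolution of the common situation where the nominal 0.8
#' keep-rule would leave an empty ensemble even though member skill is
#' respectable.
#'
#' @param runs List of `model_run` objects (or `model_runs` objects, which
#'   are flattened), each carrying `metrics$tss`.
#' @param tss_cutoff Keep threshold on held-out TSS, default 0.8.
#' @return An `ensemble_model`: `members`, `weights` (sum 1), `tss_cutoff`,
#'   `fallback_used`.
#' @export
build_ensemble <- function(runs, tss_cutoff = 0.8) {
  if (inherits(runs, "model_runs")) runs <- runs$runs
  if (length(runs) && inherits(runs[[1]], "model_runs"))
    runs <- do.call(c, lapply(runs, function(r) r$runs))
  if (!length(runs))
    stop_ensdm("build_ensemble: no runs supplied",
               class = "ensdm_validation_error")
  tss_vals <- vapply(runs, function(r) r$metrics$tss, numeric(1))
  keep <- tss_vals >= tss_cutoff
  fallback <- !any(keep)
  if (fallback) {
    message("build_ensemble: no run reached TSS cutoff ", tss_cutoff,
            " (max ", round(max(tss_vals), 3),
            "); falling back to TSS-proportional weights over all ",
            length(runs), " runs")
    keep <- rep(TRUE, length(runs))
  }
  members <- runs[keep]
  w <- pmax(tss_vals[keep], 0)
  if (sum(w) <= 0)
    stop_ensdm("build_ensemble: no member has positive TSS; ensemble ",
               "would be uninformative", class = "ensdm_validation_error")
  structure(list(members = members, weights = w / sum(w),
                 tss_cutoff = tss_cutoff, fallback_used = fallback),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d member(s), TSS cutoff %.2f%s\n",
              length(x$members), x$tss_cutoff,
              if (x$fallback_used) " (fallback: cutoff unmet)" else ""))
  invisible(x)
}

#' Ensemble prediction
#'
#' Cellwise (or rowwise) weighted mean of the member predictions — a
#' convex combination, so the ensemble never leaves the members' range.
#'
#' @param ens An [build_ensemble()] result.
#' @param newdata An `env_stack` or a data frame of predictor columns.
#' @return A [suitability_map()] for a stack input; a probability vector
#'   for a data-frame input.
#' @export
ensemble_predict <- function(ens, newdata) {
  stopifnot(inherits(ens, "ensemble_model"))
  if (inherits(newdata, "env_stack")) {
    maps <- lapply(ens$members, function(m) predict_stack(m$model, newdata))
    acc <- maps[[1]]$probability$values * ens$weights[1]
    for (i in seq_along(maps)[-1])
      acc <- acc + maps[[i]]$probability$values * ens$weights[i]
    msk <- stack_mask(newdata)
    acc[msk] <- NA_real_
    suitability_map(raster_grid(acc, msk, newdata$cell_size_km,
                                "suitability_ensemble"),
                    source = "ensemble")
  } else {
    preds <- vapply(ens$members,
                    function(m) predict_table(m$model, newdata),
                    numeric(nrow(newdata)))
    if (nrow(newdata) == 1) preds <- matrix(preds, nrow = 1)
    as.numeric(preds %*% ens$weights)
  }
}

#' Serialize an ensemble description to JSON
#'
#' Records members (family, repetition, metrics), weights, cutoff and the
#' fallback flag — the provenance needed to audit a projection.
#'
#' @param ens An `ensemble_model`.
#' @param path Output path.
#' @export
write_ensemble_json <- function(ens, path) {
  desc <- list(
    tss_cutoff = ens$tss_cutoff,
    fallback_used = ens$fallback_used,
    members = lapply(seq_along(ens$members), function(i) {
      m <- ens$members[[i]]
      list(family = m$spec$family, repetition = m$repetition,
           tss = m$metrics$tss, auc = m$metrics$auc,
           threshold = m$metrics$threshold, weight = ens$weights[i])
    }))
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Five-class suitability scheme
#'
#' Default bin edges 0.2/0.4/0.6/0.8 with labels unsuitable, low,
#' moderate, high, excellent. Bins are half-open on the right except the
#' top one: `p >= 0.8` is excellent, `0.2 <= p < 0.4` is low, `p < 0.2`
#' is unsuitable.
#'
#' @param edges Strictly increasing edges in `(0, 1)`.
#' @param labels One more label than edges.
#' @return A `class_scheme`.
#' @export
class_scheme <- function(edges = c(0.2, 0.4, 0.6, 0.8),
                         labels = c("unsuitable", "low", "moderate",
                                    "high", "excellent")) {
  stopifnot(all(diff(edges) > 0), all(edges > 0), all(edges < 1),
            length(labels) == length(edges) + 1)
  structure(list(edges = edges, labels = labels), class = "class_scheme")
}

#' Classify a suitability map into discrete classes
#'
#' @param map A [suitability_map()].
#' @param scheme A [class_scheme()].
#' @return A [raster_grid] of integer class codes `1..k` (1 = lowest
#'   class), with the labels in attribute `"labels"`.
#' @export
classify_suitability <- function(map, scheme = class_scheme()) {
  stopifnot(inherits(map, "suitability_map"), inherits(scheme, "class_scheme"))
  g <- map$probability
  cls <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  idx <- !g$mask
  # findInterval with left-closed intervals: p in [edge_k, edge_{k+1}) -> k
  cls[idx] <- findInterval(g$values[idx], scheme$edges) + 1
  out <- raster_grid(cls, g$mask, g$cell_size_km, "suitability_class")
  attr(out, "labels") <- scheme$labels
  out
}

#' Per-class areas and percentages
#'
#' @param class_raster Output of [classify_suitability()].
#' @param cell_size_km Cell size; defaults to the raster's.
#' @return Data frame with `class`, `n_cells`, `area_km2`, `percent`
#'   (percent of the non-masked study area; sums to 100).
#' @export
class_area_summary <- function(class_raster, cell_size_km = NULL) {
  stopifnot(is_raster_grid(class_raster))
  cell_size_km <- cell_size_km %||% class_raster$cell_size_km
  labels <- attr(class_raster, "labels") %||%
    as.character(seq_len(max(class_raster$values, na.rm = TRUE)))
  v <- class_raster$values[!class_raster$mask]
  if (!length(v))
    stop_ensdm("class_area_summary: no non-masked cells",
               class = "ensdm_validation_error")
  counts <- vapply(seq_along(labels), function(k) sum(v == k), numeric(1))
  data.frame(class = labels, n_cells = counts,
             area_km2 = area_km2(counts, cell_size_km),
             percent = 100 * counts / length(v))
}

#' Response curve along one predictor
#'
#' Evaluation-strip curve: the predictor is varied over `n_points` equally
#' spaced values spanning its observed min-max in the training table while
#' every other predictor is held at its training-table mean.
#'
#' @param model An `sdm_model` or `ensemble_model`.
#' @param table Training table supplying the observed ranges and means.
#' @param variable Predictor to vary.
#' @param n_points Number of grid points, default 100.
#' @return A data frame with columns `variable`, `value`, `response`.
#' @export
response_curve <- function(model, table, variable, n_points = 100) {
  vars <- predictor_names(table)
  if (!variable %in% vars)
    stop_ensdm("response_curve: unknown variable '", variable, "'",
               class = "ensdm_validation_error")
  grid <- seq(min(table[[variable]]), max(table[[variable]]),
              length.out = n_points)
  strip <- as.data.frame(lapply(table[, vars, drop = FALSE], function(col)
    rep(mean(col), n_points)))
  names(strip) <- vars
  strip[[variable]] <- grid
  attr(strip, "predictors") <- vars
  resp <- if (inherits(model, "ensemble_model"))
    ensemble_predict(model, strip)
  else
    predict_table(model, strip)
  data.frame(variable = variable, value = grid, response = resp)
}
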