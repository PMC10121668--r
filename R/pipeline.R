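# Pipeline orchestration: one validated config drives synth/load ->
# thin/background -> prune -> fit/evaluate -> ensemble -> project/classify
# -> change analysis, with every artifact written under `out_dir`.

pipeline_defaults <- function() {
  list(label = "run", seed = 1, out_dir = "ensdm_output",
       min_separation_cells = 1, n_background = NULL,
       corr_threshold = 0.8, train_fraction = 0.8, n_rep = 10,
       tss_cutoff = 0.8, class_edges = c(0.2, 0.4, 0.6, 0.8),
       families = LEARNER_FAMILIES, n_shuffles = 3,
       scenarios = list())
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent named list; checks field
#' domains, fills defaults and records which defaults were filled so the
#' run report can echo them.
#'
#' @param config YAML path or named list. Must contain either a
#'   `synthetic` block (grid size, layer specs, truth, presence count) or
#'   a `paths` block (`stack_dir`, `occurrences`); see the package
#'   vignette for the full schema.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_ensdm("validate_config: no such file: ", config,
                 class = "ensdm_io_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop_ensdm("validate_config: config must be a YAML file or a list",
               class = "ensdm_validation_error")
  defaults <- pipeline_defaults()
  filled <- setdiff(names(defaults), names(config))
  filled <- setdiff(filled, "n_background")  # NULL default, always "filled"
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(config$train_fraction > 0 && config$train_fraction < 1,
      "train_fraction: must be in (0, 1)")
  chk(config$corr_threshold > 0 && config$corr_threshold <= 1,
      "corr_threshold: must be in (0, 1]")
  chk(config$n_rep >= 1, "n_rep: must be >= 1")
  chk(config$min_separation_cells >= 1,
      "min_separation_cells: must be >= 1")
  chk(all(diff(config$class_edges) > 0) && all(config$class_edges > 0) &&
        all(config$class_edges < 1),
      "class_edges: must be strictly increasing within (0, 1)")
  bad_fam <- setdiff(toupper(config$families), LEARNER_FAMILIES)
  chk(length(bad_fam) == 0,
      paste0("families: unknown ", paste(bad_fam, collapse = ", "),
             "; registered: ", paste(LEARNER_FAMILIES, collapse = ", ")))
  chk(!is.null(config$synthetic) || !is.null(config$paths),
      "config: need a `synthetic` or a `paths` block")
  if (!is.null(config$paths)) {
    chk(!is.null(config$paths$stack_dir) &&
          dir.exists(config$paths$stack_dir),
        "paths$stack_dir: directory does not exist")
    chk(!is.null(config$paths$occurrences) &&
          file.exists(config$paths$occurrences),
        "paths$occurrences: file does not exist")
  }
  if (length(problems))
    stop_ensdm("validate_config: ", paste(problems, collapse = "; "),
               class = "ensdm_validation_error")
  config$families <- toupper(config$families)
  config$defaults_filled <- filled
  class(config) <- c("run_config", "list")
  config
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_ensdm("pipeline stage '", stage, "' failed: ",
               conditionMessage(e), class = "ensdm_pipeline_error")
  })
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    specs <- lapply(syn$layers, function(l)
      layer_spec(l$name, l$mean %||% 0, l$sd %||% 1, l$radius %||% 3))
    stack <- gen_env_stack(syn$n_rows, syn$n_cols, specs,
                           collinear_pairs = syn$collinear_pairs %||% list(),
                           seed = derive_seed(config$seed, 1),
                           cell_size_km = syn$cell_size_km %||% 1)
    truth <- truth_spec(syn$truth$coefficients,
                        syn$truth$intercept %||% 0,
                        syn$truth$quadratic %||% list())
    truth_map <- gen_true_suitability(stack, truth)
    raw <- sample_presences(truth_map, syn$n_presences %||% 90,
                            seed = derive_seed(config$seed, 2))
    list(stack = stack, raw_points = raw$points)
  } else {
    stack <- read_stack(config$paths$stack_dir)
    occ <- read_occurrences(config$paths$occurrences, "presence",
                            stack = stack)
    list(stack = stack, raw_points = occ$points)
  }
}

#' Run the full ensemble-SDM pipeline
#'
#' Executes thinning, background sampling, collinearity pruning,
#' cross-validated fitting of every requested family, permutation
#' importance, TSS-weighted ensembling, projection and five-class
#' classification of the current and every scenario stack, MAX_TSS
#' binarization, and the four-category change analysis; writes CSV/JSON/
#' raster artifacts under `config$out_dir` plus a `report.json` recording
#' seeds, defaults filled, the fallback flag and every file written.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(p) artifacts <<- c(artifacts, p)
  on_fail_marker <- file.path(out, "FAILED")
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline failed; partial outputs retained",
                              on_fail_marker), add = TRUE)

  inputs <- pipeline_stage("inputs", load_pipeline_inputs(config))
  stack <- inputs$stack

  occ <- pipeline_stage("thin", thin_occurrences(
    inputs$raw_points, config$min_separation_cells))
  bg <- pipeline_stage("background", sample_background(
    stack, occ, n = config$n_background,
    seed = derive_seed(config$seed, 3)))
  table_full <- pipeline_stage("extract", extract_table(stack, occ, bg))

  retained <- pipeline_stage("prune", prune_collinear(
    pearson_matrix(table_full), threshold = config$corr_threshold))
  table <- table_full[, c(retained, "response")]
  attr(table, "predictors") <- retained

  splits <- make_splits(nrow(table), config$train_fraction, config$n_rep,
                        seed = derive_seed(config$seed, 4),
                        stratify_by = table$response)
  cv <- pipeline_stage("cross_validate", {
    res <- lapply(config$families, function(fam)
      cross_validate(learner_spec(fam, seed = derive_seed(config$seed, 5)),
                     table, splits))
    names(res) <- config$families
    res
  })
  eval_rows <- do.call(rbind, lapply(cv, function(r) r$summary))
  utils::write.csv(eval_rows, file.path(out, "evaluation.csv"),
                   row.names = FALSE)
  emit("evaluation.csv")
  family_means <- do.call(rbind, lapply(cv, function(r)
    data.frame(family = r$summary$family[1],
               mean_auc = mean(r$summary$auc),
               sd_auc = stats::sd(r$summary$auc),
               mean_tss = mean(r$summary$tss),
               sd_tss = stats::sd(r$summary$tss))))
  utils::write.csv(family_means, file.path(out, "evaluation_summary.csv"),
                   row.names = FALSE)
  emit("evaluation_summary.csv")

  imp <- pipeline_stage("importance", {
    full_models <- lapply(config$families, function(fam)
      fit(learner_spec(fam, seed = derive_seed(config$seed, 6)), table))
    names(full_models) <- config$families
    importance_summary(importance_matrix(
      full_models, table, n_shuffles = config$n_shuffles,
      seed = derive_seed(config$seed, 7)))
  })
  write_importance_csv(imp, file.path(out, "importance.csv"))
  emit("importance.csv")

  ens <- pipeline_stage("ensemble", build_ensemble(
    do.call(c, lapply(cv, function(r) r$runs)), config$tss_cutoff))
  write_ensemble_json(ens, file.path(out, "ensemble.json"))
  emit("ensemble.json")

  # MAX_TSS threshold of the ensemble, measured on the full table, reused
  # unchanged for every projection.
  ens_train_pred <- ensemble_predict(ens, table)
  mt <- max_tss_threshold(ens_train_pred, table$response)

  scheme <- class_scheme(config$class_edges)
  scenarios <- config$scenarios
  project_one <- function(st) {
    map <- ensemble_predict(ens, st)
    cls <- classify_suitability(map, scheme)
    bin <- binarize(map, mt["threshold"])
    write_raster(map$probability,
                 file.path(out, paste0("suitability_", st$label, ".asc")))
    emit(paste0("suitability_", st$label, ".asc"))
    write_raster(cls, file.path(out, paste0("class_", st$label, ".asc")))
    emit(paste0("class_", st$label, ".asc"))
    write_raster(bin$presence,
                 file.path(out, paste0("binary_", st$label, ".asc")))
    emit(paste0("binary_", st$label, ".asc"))
    list(map = map, cls = cls, bin = bin,
         areas = class_area_summary(cls))
  }
  cur <- pipeline_stage("project_current", project_one(stack))
  utils::write.csv(cur$areas, file.path(out, "class_summary_current.csv"),
                   row.names = FALSE)
  emit("class_summary_current.csv")

  change_rows <- list()
  for (sc in scenarios) {
    scn <- scenario_spec(sc$label, sc$deltas %||% list(),
                         sc$scale_factors %||% list())
    fut_stack <- pipeline_stage(paste0("scenario_", scn$label),
                                apply_scenario(stack, scn))
    fut <- pipeline_stage(paste0("project_", scn$label),
                          project_one(fut_stack))
    cmz <- change_map(cur$bin, fut$bin)
    write_raster(cmz$categories,
                 file.path(out, paste0("change_", scn$label, ".asc")))
    emit(paste0("change_", scn$label, ".asc"))
    jsonlite::write_json(as.list(attr(cmz$categories, "legend")),
                         file.path(out,
                                   paste0("change_", scn$label, ".json")),
                         auto_unbox = TRUE)
    emit(paste0("change_", scn$label, ".json"))
    cs <- change_summary(cmz)
    change_rows[[scn$label]] <- data.frame(
      scenario = scn$label,
      stable_absence_km2 = cs$stable_absence_km2,
      stable_presence_km2 = cs$stable_presence_km2,
      loss_km2 = cs$loss_km2, gain_km2 = cs$gain_km2,
      loss_pct = cs$loss_pct, gain_pct = cs$gain_pct,
      net_change_pct = cs$net_change_pct)
    pcc <- class_percent_change(cur$areas, fut$areas)
    utils::write.csv(pcc,
                     file.path(out, paste0("class_change_", scn$label,
                                           ".csv")),
                     row.names = FALSE)
    emit(paste0("class_change_", scn$label, ".csv"))
  }
  if (length(change_rows)) {
    utils::write.csv(do.call(rbind, change_rows),
                     file.path(out, "change_summary.csv"),
                     row.names = FALSE)
    emit("change_summary.csv")
  }

  report <- list(
    label = config$label, seed = config$seed,
    defaults_filled = config$defaults_filled,
    families = config$families, retained_predictors = retained,
    n_presences = nrow(occ$points), n_background = nrow(bg$points),
    tss_cutoff = config$tss_cutoff,
    ensemble_fallback_used = ens$fallback_used,
    max_tss_threshold = unname(mt["threshold"]),
    max_tss_value = unname(mt["tss"]),
    package_version = as.character(utils::packageVersion("ensdm")),
    artifacts = artifacts)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  if (file.exists(on_fail_marker)) unlink(on_fail_marker)
  invisible(report)
}
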