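# Shared synthetic study systems. The strong-signal system is the frozen
# simulation condition used by the recovery checks: eight unit-sd layers
# (smoothing radius 3) on a 64x64 km grid, a logistic truth driven by two
# of them (standardized coefficients +2.5 / -2.5, intercept -5, landscape
# prevalence ~10%), 200 presences sampled proportional to suitability and
# 200 uniform background points.

tiny_grid <- function(values, cell = 1, name = "g") {
  raster_grid(matrix(values, nrow = sqrt(length(values))), cell_size_km = cell,
              name = name)
}

make_small_stack <- function(seed = 1, n = 24, layers = 3) {
  specs <- lapply(seq_len(layers), function(i)
    layer_spec(paste0("env", i), mean = i * 10, sd = 2 + i, radius = 2))
  gen_env_stack(n, n, specs, seed = seed)
}

strong_signal_truth <- function() {
  truth_spec(list(env1 = 2.5, env2 = -2.5), intercept = -5)
}

make_signal_table <- function(seed, n_layers = 8, n_pres = 200, n_bg = 200,
                              n = 64) {
  specs <- lapply(seq_len(n_layers), function(i)
    layer_spec(paste0("env", i), 0, 1, 3))
  st <- gen_env_stack(n, n, specs, seed = seed)
  tm <- gen_true_suitability(st, strong_signal_truth())
  occ <- sample_presences(tm, n_pres, seed = seed + 1000)
  bg <- sample_background(st, occ, n = n_bg, seed = seed + 2000)
  list(stack = st, table = extract_table(st, occ, bg))
}

# Warming system for the range-shift checks: temperature is a lapse-rate
# transform of a smooth elevation field plus local noise; the truth has a
# thermal optimum at the current mean temperature, so uniform warming
# moves the suitable band upslope. The +2.76 degC delta is the study
# region's stated current-to-2050s mean-temperature trend.
make_warming_system <- function(seed) {
  base <- gen_env_stack(64, 64,
    list(layer_spec("elev", 1500, 600, 4),
         layer_spec("noise1", 0, 1, 3),
         layer_spec("tnoise", 0, 1, 3)), seed = seed)
  elev <- base$layers$elev$values
  temp <- 25 - 0.0065 * elev + base$layers$tnoise$values
  st <- assemble_stack(list(raster_grid(temp, name = "temp"),
                            base$layers$elev, base$layers$noise1),
                       "current")
  truth <- truth_spec(list(temp = 0), intercept = 1,
                      quadratic = list(temp = -2))
  list(stack = st, truth = truth)
}

WARMING_DELTA_C <- 2.76

all_families <- function() c("GLM", "GBM", "RF", "SRE", "CTA", "ANN",
                             "FDA", "MARS", "GAM", "MAXENT")

# Independent metric oracles -------------------------------------------

# AUC by exhaustive pairwise comparison (ties count 0.5).
auc_bruteforce <- function(pred, labels) {
  pos <- pred[labels == 1]; neg <- pred[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Best TSS found by a dense fixed-grid scan (oracle for the exact
# midpoint maximizer).
max_tss_gridscan <- function(pred, labels, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, function(t) tss(pred, labels, t), numeric(1))
  max(vals)
}
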