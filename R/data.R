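# Bundled reference tables from a published ensemble-SDM study of the
# medicinal shrub Stachys inflata in Isfahan province (central Iran):
# the per-algorithm variable-importance table and the habitat-change
# summary. They serve as worked-example inputs and as fixtures for the
# arithmetic the package's summary functions implement.

#' Reference variable-importance table (Stachys inflata, Isfahan)
#'
#' Importance (%) of ten environmental layers across the ten learner
#' families, as reported for an ensemble distribution model of
#' *Stachys inflata*, plus the report's own "Relative importance" (mean
#' over algorithms) and "Contribution" (percent of summed means) rows.
#'
#' @return List with `per_algorithm` (10 x 10 numeric matrix, algorithms
#'   by variables), `reported_mean` and `reported_contribution` (named
#'   numeric vectors).
#' @export
stachys_importance <- function() {
  path <- system.file("extdata", "stachys_importance.csv",
                      package = "ensdm", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$algorithm
  list(per_algorithm = m[seq_len(nrow(m) - 2), , drop = FALSE],
       reported_mean = m["Relative importance", ],
       reported_contribution = m["Contribution", ])
}

#' Reference habitat-change table (Stachys inflata, Isfahan)
#'
#' Stable-absence/stable-presence areas (km²) and habitat loss, gain and
#' net-change percentages for two general circulation models, three SSP
#' scenarios and two horizons, as reported for the same reference study.
#' Loss/gain percentages are relative to the current suitable area, so
#' `net = gain - loss` up to rounding of the printed inputs; one row
#' (MRI-ESM2-0 / SSP126 / 2050) violates that identity by several points
#' and is best treated as a typographical error.
#'
#' @return Data frame with columns `gcm`, `scenario`, `year`,
#'   `stable_absence_km2`, `stable_presence_km2`, `loss_pct`, `gain_pct`,
#'   `net_change_pct`.
#' @export
stachys_change <- function() {
  path <- system.file("extdata", "stachys_change.csv",
                      package = "ensdm", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
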