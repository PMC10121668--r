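#' Pearson correlation matrix of the training predictors
#'
#' Computed over all rows (presence + background) of the training table.
#'
#' @param table Training table from [extract_table()] (or any data frame
#'   whose predictor columns are numeric).
#' @return Object of class `correlation_matrix`: list with `variables` and
#'   the symmetric matrix `r`.
#' @export
pearson_matrix <- function(table) {
  vars <- predictor_names(table)
  x <- as.matrix(table[, vars, drop = FALSE])
  if (nrow(x) < 3)
    stop_ensdm("pearson_matrix: need at least 3 rows",
               class = "ensdm_validation_error")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_ensdm("pearson_matrix: constant column(s): ",
               paste(vars[sds == 0], collapse = ", "),
               class = "ensdm_validation_error")
  r <- stats::cor(x)
  structure(list(variables = vars, r = r), class = "correlation_matrix")
}

#' Drop one member of every highly collinear pair
#'
#' Pairs with `|r| > threshold` are visited in decreasing `|r|` (ties
#' broken by variable order); when both members are still retained, the
#' one later in `priority` is dropped. The result is guaranteed to have
#' all pairwise `|r| <= threshold`.
#'
#' @param corr A [pearson_matrix()] result (or a plain correlation matrix
#'   with dimnames).
#' @param threshold Collinearity cutoff, default 0.8.
#' @param priority Character vector: permutation of the variables giving
#'   the keep order (earlier = kept). Defaults to the matrix order, the
#'   convention being that the user lists layers in decreasing ecological
#'   priority.
#' @return Character vector of retained variable names, in original order.
#' @export
prune_collinear <- function(corr, threshold = 0.8, priority = NULL) {
  if (inherits(corr, "correlation_matrix")) {
    vars <- corr$variables; r <- corr$r
  } else {
    r <- as.matrix(corr); vars <- rownames(r)
  }
  priority <- priority %||% vars
  if (!setequal(priority, vars) || length(priority) != length(vars))
    stop_ensdm("prune_collinear: `priority` must be a permutation of the ",
               "variables", class = "ensdm_validation_error")
  prio <- match(vars, priority)
  pairs <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(r[pairs]), pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
  }
  retained <- rep(TRUE, length(vars))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (retained[i] && retained[j]) {
      drop <- if (prio[i] > prio[j]) i else j
      retained[drop] <- FALSE
    }
  }
  vars[retained]
}

#' Permutation importance of one predictor
#'
#' BIOMOD-style score: predictions on the intact table are correlated with
#' predictions on a table whose single column has been randomly permuted;
#' the importance is `100 * mean(1 - r)` over shuffles, with negative
#' correlations clamped so each term stays in `[0, 1]`. A variable the
#' model ignores scores ~0; a variable the model depends on completely
#' scores ~100. If the intact predictions have zero variance the score is
#' defined as 0.
#'
#' @param model A fitted model from [fit()].
#' @param table Training table the model was fitted on.
#' @param variable Predictor name to permute.
#' @param n_shuffles Number of random permutations averaged (default 3).
#' @param seed Integer seed.
#' @return Importance in `[0, 100]`.
#' @export
permutation_importance <- function(model, table, variable, n_shuffles = 3,
                                   seed = 1) {
  if (!variable %in% predictor_names(table))
    stop_ensdm("permutation_importance: unknown variable '", variable, "'",
               class = "ensdm_validation_error")
  p0 <- predict_table(model, table)
  if (stats::sd(p0) == 0) return(0)
  terms <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    shuffled <- table
    shuffled[[variable]] <- sample(shuffled[[variable]])
    p1 <- predict_table(model, shuffled)
    if (stats::sd(p1) == 0) return(1)
    min(1, 1 - stats::cor(p0, p1))
  }, numeric(1)))
  100 * mean(terms)
}

#' Per-algorithm importance matrix for a set of fitted models
#'
#' Convenience wrapper computing [permutation_importance()] for every
#' (model, variable) pair on the full training table. Per-variable seeds
#' are derived from `seed` so the same permutations are reused across
#' algorithms.
#'
#' @param models Named list of fitted models (one per algorithm family).
#' @param table Training table.
#' @inheritParams permutation_importance
#' @return Matrix `algorithm x variable` of scores in `[0, 100]`.
#' @export
importance_matrix <- function(models, table, n_shuffles = 3, seed = 1) {
  vars <- predictor_names(table)
  out <- matrix(NA_real_, length(models), length(vars),
                dimnames = list(names(models), vars))
  for (i in seq_along(models))
    for (j in seq_along(vars))
      out[i, j] <- permutation_importance(models[[i]], table, vars[j],
                                          n_shuffles = n_shuffles,
                                          seed = derive_seed(seed, j))
  out
}

#' Mean relative importance and contribution percentages
#'
#' Summarises an algorithm-by-variable importance matrix the way ensemble
#' SDM reports do: `mean_row` is the unweighted mean score per variable
#' across algorithms, and `contribution_row` rescales the means to
#' percentages summing to 100.
#'
#' @param per_algorithm Numeric matrix `algorithm x variable` (scores in
#'   `[0, 100]`), with column names.
#' @return Object of class `importance_table` with fields `per_algorithm`,
#'   `mean_row`, `contribution_row`.
#' @export
importance_summary <- function(per_algorithm) {
  per_algorithm <- as.matrix(per_algorithm)
  if (nrow(per_algorithm) < 1 || ncol(per_algorithm) < 1)
    stop_ensdm("importance_summary: need at least one algorithm and one ",
               "variable", class = "ensdm_validation_error")
  mean_row <- colMeans(per_algorithm)
  total <- sum(mean_row)
  if (total == 0)
    stop_ensdm("importance_summary: all mean importances are zero; ",
               "contribution undefined", class = "ensdm_validation_error")
  structure(list(per_algorithm = per_algorithm,
                 mean_row = mean_row,
                 contribution_row = 100 * mean_row / total),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  m <- rbind(x$per_algorithm,
             `Relative importance` = x$mean_row,
             Contribution = x$contribution_row)
  print(round(m, 2))
  invisible(x)
}

#' Cumulative contribution of the top-k variables
#'
#' @param tbl An [importance_summary()] result.
#' @param k Number of leading variables (by contribution).
#' @return Sum of the `k` largest contribution percentages.
#' @export
top_k_contribution <- function(tbl, k) {
  stopifnot(inherits(tbl, "importance_table"),
            k >= 1, k <= length(tbl$contribution_row))
  sum(sort(tbl$contribution_row, decreasing = TRUE)[seq_len(k)])
}

#' Write an importance table as CSV
#'
#' Layout mirrors the standard report: one row per algorithm plus
#' `Relative importance` and `Contribution` summary rows.
#'
#' @param tbl An [importance_summary()] result.
#' @param path Output CSV path.
#' @export
write_importance_csv <- function(tbl, path) {
  m <- rbind(tbl$per_algorithm,
             `Relative importance` = tbl$mean_row,
             Contribution = tbl$contribution_row)
  utils::write.csv(data.frame(algorithm = rownames(m), round(m, 4),
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
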