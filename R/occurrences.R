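#' Occurrence set
#'
#' Presence or background points as 1-based `(row, col)` grid cells.
#' Duplicate cells are not allowed.
#'
#' @param points Two-column matrix or data frame of `(row, col)` cells;
#'   may have zero rows.
#' @param label `"presence"` or `"background"`.
#' @return Object of class `occurrence_set` with fields `points` (integer
#'   matrix with columns `row`, `col`) and `label`.
#' @export
occurrence_set <- function(points, label = c("presence", "background")) {
  label <- match.arg(label)
  pts <- as.matrix(points)
  if (length(pts) == 0) pts <- matrix(integer(0), 0, 2)
  if (ncol(pts) != 2)
    stop_ensdm("occurrence_set: points must have two columns (row, col)",
               class = "ensdm_validation_error")
  storage.mode(pts) <- "integer"
  dimnames(pts) <- list(NULL, c("row", "col"))
  if (anyDuplicated(pts))
    stop_ensdm("occurrence_set: duplicate cells not allowed",
               class = "ensdm_validation_error")
  structure(list(points = pts, label = label), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d %s point(s)\n", nrow(x$points), x$label))
  invisible(x)
}

occ_linear_index <- function(occ, n_rows) {
  (occ$points[, "col"] - 1L) * n_rows + occ$points[, "row"]
}

#' Thin occurrence records to a minimum separation
#'
#' Removes exact duplicates, then makes a single greedy pass in input
#' order, keeping a point iff its Chebyshev (chessboard) distance to every
#' already-kept point is at least `min_separation_cells`. With 1-km cells
#' and `min_separation_cells = 1` this drops only same-cell records, the
#' "closer than 1 km" filter of field protocols; larger values enforce
#' coarser spacing. Greedy-in-input-order makes the result deterministic.
#'
#' @param points Two-column matrix/data frame of `(row, col)` cells.
#' @param min_separation_cells Minimum Chebyshev separation (>= 1).
#' @return An [occurrence_set()] with label `"presence"`, in keep order.
#' @export
thin_occurrences <- function(points, min_separation_cells = 1) {
  stopifnot(min_separation_cells >= 1)
  pts <- as.matrix(points)
  if (length(pts) == 0)
    return(occurrence_set(matrix(integer(0), 0, 2), "presence"))
  storage.mode(pts) <- "integer"
  pts <- pts[!duplicated(pts), , drop = FALSE]
  kept <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    if (nrow(kept) == 0) {
      kept <- pts[i, , drop = FALSE]
      next
    }
    d <- pmax(abs(kept[, 1] - pts[i, 1]), abs(kept[, 2] - pts[i, 2]))
    if (all(d >= min_separation_cells))
      kept <- rbind(kept, pts[i, , drop = FALSE])
  }
  occurrence_set(kept, "presence")
}

#' Sample background (pseudo-absence) points
#'
#' Draws `n` distinct cells uniformly at random from the non-masked cells
#' not occupied by any presence — the "locations where there are no
#' presence data" convention, with no exclusion buffer. The default `n`
#' equals the number of presences (equal-count background).
#'
#' @param stack An `env_stack` supplying the grid and mask.
#' @param presences An [occurrence_set()] of presences.
#' @param n Number of background points (default `nrow(presences$points)`).
#' @param seed Integer seed.
#' @return An [occurrence_set()] with label `"background"`.
#' @export
sample_background <- function(stack, presences, n = NULL, seed = 1) {
  stopifnot(inherits(presences, "occurrence_set"))
  n <- n %||% nrow(presences$points)
  stopifnot(n >= 1)
  msk <- stack_mask(stack)
  eligible <- which(!msk)
  eligible <- setdiff(eligible, occ_linear_index(presences, nrow(msk)))
  if (length(eligible) < n)
    stop_ensdm("sample_background: need ", n, " cells but only ",
               length(eligible), " eligible (short by ",
               n - length(eligible), ")", class = "ensdm_validation_error")
  take <- with_seed(seed, sample(eligible, n, replace = FALSE))
  occurrence_set(cbind(row = (take - 1L) %% nrow(msk) + 1L,
                       col = (take - 1L) %/% nrow(msk) + 1L),
                 label = "background")
}

#' Extract the model training table
#'
#' One row per point, one column per stack layer (in stack order), plus a
#' `response` column: 1 for presence, 0 for background.
#'
#' @param stack An `env_stack`.
#' @param presences,background [occurrence_set()] objects on non-masked
#'   cells.
#' @return A data frame; attribute `"predictors"` holds the predictor
#'   column names in stack order.
#' @export
extract_table <- function(stack, presences, background) {
  msk <- stack_mask(stack)
  check_points <- function(occ) {
    idx <- occ_linear_index(occ, nrow(msk))
    out <- occ$points[, "row"] < 1 | occ$points[, "row"] > nrow(msk) |
      occ$points[, "col"] < 1 | occ$points[, "col"] > ncol(msk)
    if (any(out))
      stop_ensdm("extract_table: point outside grid: (",
                 paste(occ$points[which(out)[1], ], collapse = ", "), ")",
                 class = "ensdm_validation_error")
    bad <- msk[idx]
    if (any(bad))
      stop_ensdm("extract_table: ", occ$label, " point on masked cell: (",
                 paste(occ$points[which(bad)[1], ], collapse = ", "), ")",
                 class = "ensdm_validation_error")
    idx
  }
  idx <- c(check_points(presences), check_points(background))
  cols <- lapply(stack$layers, function(g) g$values[idx])
  tbl <- as.data.frame(cols, optional = TRUE)
  names(tbl) <- layer_names(stack)
  tbl$response <- rep(c(1L, 0L),
                      c(nrow(presences$points), nrow(background$points)))
  attr(tbl, "predictors") <- layer_names(stack)
  tbl
}

predictor_names <- function(table) {
  attr(table, "predictors") %||% setdiff(names(table), "response")
}

#' Read and write occurrence CSV files
#'
#' The grid dialect has header `row,col,label`; the geographic dialect
#' (`lon,lat,label`) is converted on read using the grid origin and cell
#' size of `stack` (row 1 at the northern edge).
#'
#' @param path CSV path.
#' @param label Which label to keep (`"presence"` or `"background"`).
#' @param stack Required for the geographic dialect.
#' @param origin `(lon, lat)` of the grid's north-west corner for the
#'   geographic dialect.
#' @return An [occurrence_set()].
#' @export
read_occurrences <- function(path, label = "presence", stack = NULL,
                             origin = c(0, 0)) {
  df <- utils::read.csv(path)
  if (all(c("row", "col") %in% names(df))) {
    pts <- df[, c("row", "col")]
  } else if (all(c("lon", "lat") %in% names(df))) {
    if (is.null(stack))
      stop_ensdm("read_occurrences: geographic dialect needs `stack`",
                 class = "ensdm_validation_error")
    deg <- stack$cell_size_km / KM_PER_DEGREE
    pts <- data.frame(row = floor((origin[2] - df$lat) / deg) + 1L,
                      col = floor((df$lon - origin[1]) / deg) + 1L)
  } else {
    stop_ensdm("read_occurrences: need columns row,col or lon,lat in ",
               path, class = "ensdm_format_error")
  }
  if ("label" %in% names(df)) pts <- pts[df$label == label, , drop = FALSE]
  occurrence_set(pts[!duplicated(pts), , drop = FALSE], label)
}

#' @rdname read_occurrences
#' @param occ An [occurrence_set()] to write (grid dialect).
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(data.frame(occ$points, label = occ$label), path,
                   row.names = FALSE)
  invisible(path)
}
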