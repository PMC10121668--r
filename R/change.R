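# MAX_TSS binarization and the four-category current-vs-future habitat
# change analysis (stable absence / stable presence / loss / gain).

#' Binarize a suitability map
#'
#' Presence (1) iff `p >= threshold` — the same `>=` convention used in
#' [confusion_at()], so the MAX_TSS threshold from model evaluation can be
#' reused unchanged here.
#'
#' @param map A [suitability_map()].
#' @param threshold Cutoff in `[0, 1]` (typically the MAX_TSS threshold
#'   of the current-climate ensemble evaluation, reused for every
#'   projection).
#' @return A `binary_map`: `presence` ([raster_grid] of 0/1) and
#'   `threshold_used`.
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "suitability_map"),
            threshold >= 0, threshold <= 1)
  g <- map$probability
  b <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  idx <- !g$mask
  b[idx] <- as.numeric(g$values[idx] >= threshold)
  structure(list(presence = raster_grid(b, g$mask, g$cell_size_km, "binary"),
                 threshold_used = threshold),
            class = "binary_map")
}

#' Current-vs-future change map
#'
#' Categorizes every non-masked cell by its suitable/unsuitable
#' transition: stable presence (1,1), loss (1,0), gain (0,1), stable
#' absence (0,0).
#'
#' @param current,future `binary_map` objects on identical grids.
#' @return A `change_map`: [raster_grid] of integer codes (0 stable
#'   absence, 1 gain, 2 loss, 3 stable presence) with a `"legend"`
#'   attribute.
#' @export
change_map <- function(current, future) {
  stopifnot(inherits(current, "binary_map"), inherits(future, "binary_map"))
  cg <- current$presence; fg <- future$presence
  if (!identical(dim(cg$values), dim(fg$values)) ||
      !identical(cg$mask, fg$mask))
    stop_ensdm("change_map: current and future grids differ in shape or ",
               "mask", class = "ensdm_alignment_error")
  codes <- matrix(NA_real_, nrow(cg$values), ncol(cg$values))
  idx <- !cg$mask
  # 0 stable_absence, 1 gain, 2 loss, 3 stable_presence
  codes[idx] <- 2 * cg$values[idx] + fg$values[idx]
  out <- raster_grid(codes, cg$mask, cg$cell_size_km, "change")
  attr(out, "legend") <- c(`0` = "stable_absence", `1` = "gain",
                           `2` = "loss", `3` = "stable_presence")
  structure(list(categories = out), class = "change_map")
}

#' Habitat-change summary (areas and percentages)
#'
#' Areas in km² for the four categories plus loss/gain/net percentages.
#' Percent denominators are the current suitable area
#' (`stable_presence + loss`), which makes `net = gain - loss` an exact
#' identity.
#'
#' @param cm A [change_map()] result.
#' @param cell_size_km Cell size; defaults to the raster's.
#' @return A `change_summary` list: `stable_absence_km2`,
#'   `stable_presence_km2`, `loss_km2`, `gain_km2`, `loss_pct`,
#'   `gain_pct`, `net_change_pct`.
#' @export
change_summary <- function(cm, cell_size_km = NULL) {
  stopifnot(inherits(cm, "change_map"))
  g <- cm$categories
  cell_size_km <- cell_size_km %||% g$cell_size_km
  v <- g$values[!g$mask]
  n <- c(stable_absence = sum(v == 0), gain = sum(v == 1),
         loss = sum(v == 2), stable_presence = sum(v == 3))
  current_suitable <- n["stable_presence"] + n["loss"]
  if (current_suitable == 0)
    stop_ensdm("change_summary: current suitable area is zero; loss/gain ",
               "percentages undefined", class = "ensdm_validation_error")
  a <- area_km2(n, cell_size_km)
  loss_pct <- unname(100 * a["loss"] / (a["stable_presence"] + a["loss"]))
  gain_pct <- unname(100 * a["gain"] / (a["stable_presence"] + a["loss"]))
  structure(list(stable_absence_km2 = unname(a["stable_absence"]),
                 stable_presence_km2 = unname(a["stable_presence"]),
                 loss_km2 = unname(a["loss"]),
                 gain_km2 = unname(a["gain"]),
                 loss_pct = loss_pct, gain_pct = gain_pct,
                 net_change_pct = gain_pct - loss_pct),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(paste0("<change_summary> stable absence %.0f km2, stable ",
                     "presence %.0f km2,\n  loss %.3f%%, gain %.3f%%, ",
                     "net %.3f%%\n"),
              x$stable_absence_km2, x$stable_presence_km2,
              x$loss_pct, x$gain_pct, x$net_change_pct))
  invisible(x)
}

#' Per-class percent change between two class-area summaries
#'
#' `100 * (future - current) / current` per suitability class. Classes
#' with zero current area are reported as `NA` with a flag rather than
#' infinities.
#'
#' @param current_summary,future_summary Data frames from
#'   [class_area_summary()] (matching classes in matching order).
#' @return Data frame with `class`, `current_km2`, `future_km2`,
#'   `pct_change`, `undefined` (logical).
#' @export
class_percent_change <- function(current_summary, future_summary) {
  stopifnot(identical(current_summary$class, future_summary$class))
  cur <- current_summary$area_km2
  fut <- future_summary$area_km2
  undef <- cur == 0
  pct <- ifelse(undef, NA_real_, 100 * (fut - cur) / cur)
  data.frame(class = current_summary$class, current_km2 = cur,
             future_km2 = fut, pct_change = pct, undefined = undef)
}
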