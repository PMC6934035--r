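#' Summarise trial records into per-cell statistics
#'
#' A "cell" is one analysis unit crossed with one instruction condition.
#' The unit is either the individual item or the sentence-type x variant
#' combination; sentence type is the design's main unit of analysis, so it
#' is the default, with item-level aggregation available for analyses that
#' treat each stimulus as a point on the state trace.
#'
#' @param records Tibble of rating records. Attention-check trials are
#'   dropped before aggregation.
#' @param unit `"sentence_type_variant"` (default) or `"item"`.
#' @return A tibble with one row per observed (unit, condition):
#'   `unit_id`, `condition`, `mean`, `n`, `variance` (sample variance with
#'   the n-1 denominator, 0 when n = 1).
#' @examples
#' recs <- sample_ratings(sample_latents(5, rho = 0.9, seed = 1),
#'                        n_per_cell = 13, seed = 2)
#' aggregate_cells(recs)
#' @export
aggregate_cells <- function(records, unit = c("sentence_type_variant", "item")) {
  unit <- match.arg(unit)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(unit_id = character(), condition = character(),
                          mean = double(), n = integer(), variance = double()))
  }
  records <- dplyr::filter(records, !.data$is_attention_check)
  records$unit_id <- if (unit == "item") {
    records$item_id
  } else {
    paste(records$sentence_type, records$variant, sep = ":")
  }
  records |>
    dplyr::group_by(.data$unit_id, .data$condition) |>
    dplyr::summarise(
      mean = mean(.data$rating),
      n = dplyr::n(),
      variance = if (dplyr::n() > 1) var(.data$rating) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$unit_id, .data$condition)
}

#' Build paired state-trace points from cell summaries
#'
#' Pivots per-cell means into one row per unit with the acceptability mean
#' on x and the grammaticality mean on y, the coordinates of the state-trace
#' plot. Units observed in only one condition cannot be placed on the trace
#' and are dropped with a warning.
#'
#' @param cells Output of [aggregate_cells()].
#' @param weight_scheme `"n"` (default) weights each coordinate by its cell
#'   count; `"inv_se2"` uses the inverse squared standard error
#'   (n / variance), falling back to the cell count when a cell's variance
#'   is zero.
#' @return Tibble with columns `unit_id`, `x`, `y`, `wx`, `wy` and
#'   attributes `n_x`, `n_y` (cell counts, used by the bootstrap).
#' @export
state_trace_points <- function(cells, weight_scheme = c("n", "inv_se2")) {
  weight_scheme <- match.arg(weight_scheme)
  wide <- tidyr::pivot_wider(
    cells,
    id_cols = "unit_id", names_from = "condition",
    values_from = c("mean", "n", "variance")
  )
  needed <- c("mean_acceptability", "mean_grammaticality")
  if (!all(needed %in% names(wide))) {
    abort("state trace needs units rated in both conditions",
          class = "statrace_validation_error")
  }
  incomplete <- is.na(wide$mean_acceptability) | is.na(wide$mean_grammaticality)
  if (any(incomplete)) {
    warn(paste0(sum(incomplete), " unit(s) missing one condition; dropped: ",
                paste(head(wide$unit_id[incomplete], 5), collapse = ", ")))
    wide <- wide[!incomplete, ]
  }
  if (nrow(wide) < 2) {
    abort("fewer than 2 units with both conditions",
          class = "statrace_validation_error")
  }
  weight <- function(n, v) {
    if (weight_scheme == "n") return(as.double(n))
    ifelse(v > 0, n / v, as.double(n))
  }
  pts <- tibble::tibble(
    unit_id = wide$unit_id,
    x = wide$mean_acceptability,
    y = wide$mean_grammaticality,
    wx = weight(wide$n_acceptability, wide$variance_acceptability),
    wy = weight(wide$n_grammaticality, wide$variance_grammaticality)
  )
  attr(pts, "n_x") <- wide$n_acceptability
  attr(pts, "n_y") <- wide$n_grammaticality
  pts
}
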