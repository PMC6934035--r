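# statistic only, skipping result-object construction (bootstrap hot path)
cmr_stat <- function(x, y, wx, wy, exact_n_max = 9, restarts = 20) {
  if (length(x) <= exact_n_max) {
    cmr_exact_cpp(x, y, wx, wy)$sse
  } else {
    starts <- rbind(order(x, y), order(y, x), order(rank(x) + rank(y)))
    cmr_heuristic_cpp(x, y, wx, wy, starts, as.integer(restarts))$sse
  }
}

#' Bootstrap state-trace dimensionality test
#'
#' Tests whether acceptability and grammaticality ratings are consistent
#' with a single latent dimension. The observed statistic is the lack of
#' fit of the one-dimensional model (both cell-mean vectors monotone under
#' one common unit order, [coupled_fit()]) minus that of the
#' two-dimensional alternative (0 without a-priori constraints). A
#' bootstrap population of the same statistic is generated by resampling
#' ratings; the p value is the proportion of bootstrap statistics at least
#' as large as the observed one, so small p means the observed rank-order
#' violations are extreme under the one-dimensional null.
#'
#' Three resampling schemes are available. `"data_informed"` (default, the
#' scheme of the frequentist state-trace literature this test follows)
#' resamples each cell's residuals with replacement and recentres them on
#' the one-dimensional model's fitted cell means, so bootstrap data are
#' generated under the null. `"cells"` resamples ratings within each
#' unit x condition cell around the observed means (sizes preserved); it
#' is markedly conservative because the observed violations are baked into
#' every resample. `"participants"` resamples whole participants with
#' replacement.
#'
#' Cells with fewer ratings than `min_cell` (default 8, the minimum found
#' by simulation to avoid degenerate resampling) are flagged with a
#' warning, not dropped.
#'
#' @param records Filtered (post-exclusion) rating records.
#' @param unit Analysis unit passed to [aggregate_cells()].
#' @param n_boot Bootstrap iterations.
#' @param seed Optional integer seed (recorded in the result).
#' @param scheme Resampling scheme, see Details.
#' @param comparison `"non_strict"` counts bootstrap statistics `>=` the
#'   observed one (default: perfectly monotone data then give p = 1);
#'   `"strict"` counts only `>`.
#' @param weight_scheme Passed to [state_trace_points()].
#' @param min_cell Minimum cell size before a flag is raised.
#' @param exact_n_max,restarts Passed to the coupled fit.
#' @return An object of class `sta_result`: observed statistic, bootstrap
#'   statistics, p value, settings, the state-trace points and the full
#'   `cmr_result` of the observed fit.
#' @export
sta_test <- function(records, unit = c("sentence_type_variant", "item"),
                     n_boot = 1000, seed = NULL,
                     scheme = c("data_informed", "cells", "participants"),
                     comparison = c("non_strict", "strict"),
                     weight_scheme = c("n", "inv_se2"), min_cell = 8,
                     exact_n_max = 9, restarts = 20) {
  unit <- match.arg(unit)
  scheme <- match.arg(scheme)
  comparison <- match.arg(comparison)
  weight_scheme <- match.arg(weight_scheme)
  if (n_boot < 1) abort("n_boot must be >= 1", class = "statrace_domain_error")
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  local_seed_if(seed)

  cells <- aggregate_cells(records, unit)
  pts <- state_trace_points(cells, weight_scheme)
  flagged <- cells |>
    dplyr::filter(.data$unit_id %in% pts$unit_id, .data$n < min_cell)
  if (nrow(flagged) > 0) {
    warn(paste0(nrow(flagged), " cell(s) below the minimum size ", min_cell,
                " for non-degenerate resampling"))
  }
  fit <- coupled_fit(pts, exact_n_max = exact_n_max, restarts = restarts)
  observed <- fit$statistic

  # per-cell rating vectors for the retained units, in the row order of pts
  records$unit_key <- if (unit == "item") {
    records$item_id
  } else {
    paste(records$sentence_type, records$variant, sep = ":")
  }
  cell_vals <- function(cond) {
    lapply(pts$unit_id, function(u) {
      records$rating[records$unit_key == u & records$condition == cond]
    })
  }
  vx <- cell_vals("acceptability")
  vy <- cell_vals("grammaticality")
  nx <- lengths(vx)
  ny <- lengths(vy)
  rx <- lapply(vx, function(v) v - mean(v))  # within-cell residuals
  ry <- lapply(vy, function(v) v - mean(v))

  boot_one <- switch(scheme,
    cells = function() {
      bx <- vapply(seq_along(vx), function(i) {
        mean(vx[[i]][sample.int(nx[i], nx[i], replace = TRUE)])
      }, 0)
      by <- vapply(seq_along(vy), function(i) {
        mean(vy[[i]][sample.int(ny[i], ny[i], replace = TRUE)])
      }, 0)
      cmr_stat(bx, by, pts$wx, pts$wy, exact_n_max, restarts)
    },
    data_informed = function() {
      bx <- vapply(seq_along(vx), function(i) {
        fit$fitted_x[i] + mean(rx[[i]][sample.int(nx[i], nx[i], replace = TRUE)])
      }, 0)
      by <- vapply(seq_along(vy), function(i) {
        fit$fitted_y[i] + mean(ry[[i]][sample.int(ny[i], ny[i], replace = TRUE)])
      }, 0)
      cmr_stat(bx, by, pts$wx, pts$wy, exact_n_max, restarts)
    },
    participants = function() {
      pid <- unique(records$participant_id)
      take <- pid[sample.int(length(pid), length(pid), replace = TRUE)]
      boot_rec <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
        r <- records[records$participant_id == take[k], ]
        r$participant_id <- paste0(r$participant_id, "#", k)
        r
      }))
      bcells <- aggregate_cells(boot_rec, unit)
      bpts <- suppressWarnings(
        tryCatch(state_trace_points(bcells, weight_scheme),
                 error = function(e) NULL))
      if (is.null(bpts)) return(NA_real_)
      cmr_stat(bpts$x, bpts$y, bpts$wx, bpts$wy, exact_n_max, restarts)
    })

  boot <- vapply(seq_len(n_boot), function(b) boot_one(), 0)
  boot <- boot[!is.na(boot)]
  tol <- 1e-12
  p <- if (comparison == "non_strict") {
    mean(boot >= observed - tol)
  } else {
    mean(boot > observed + tol)
  }

  structure(list(
    observed_statistic = observed,
    boot_statistics = boot,
    p_value = p,
    n_boot = n_boot,
    seed = seed,
    unit = unit,
    scheme = scheme,
    comparison = comparison,
    weight_scheme = weight_scheme,
    min_cell = min_cell,
    cells_below_min = flagged,
    points = pts,
    fit = fit
  ), class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat("State-trace dimensionality test\n")
  cat(sprintf("  units: %d (%s), bootstrap: %d (%s, %s comparison)\n",
              nrow(x$points), x$unit, x$n_boot, x$scheme, x$comparison))
  cat(sprintf("  observed statistic: %.6g, p = %.4g\n",
              x$observed_statistic, x$p_value))
  if (nrow(x$cells_below_min) > 0) {
    cat(sprintf("  %d cell(s) below minimum size %d\n",
                nrow(x$cells_below_min), x$min_cell))
  }
  invisible(x)
}

#' @describeIn sta_test Per-unit state-trace coordinates with the fitted
#'   one-dimensional values.
#' @param x An `sta_result`.
#' @param ... Unused.
#' @method tidy sta_result
#' @export
tidy.sta_result <- function(x, ...) {
  tidy(x$fit)
}

#' @describeIn sta_test One-row test summary.
#' @method glance sta_result
#' @export
glance.sta_result <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$points),
    observed_statistic = x$observed_statistic,
    p_value = x$p_value,
    n_boot = x$n_boot,
    scheme = x$scheme,
    comparison = x$comparison,
    n_cells_below_min = nrow(x$cells_below_min)
  )
}

#' Power and calibration of the state-trace test across latent correlations
#'
#' Simulates rating experiments whose two latent factors are correlated at
#' each value of `rho_grid`, runs [sta_test()] on each, and reports the
#' rejection rate at `alpha`. At `rho = 1` the generator is a true
#' one-factor world and the rejection rate estimates the type-I error; as
#' `rho` decreases the state trace fattens into a two-dimensional ribbon
#' and the rejection rate traces the test's power.
#'
#' @param rho_grid Latent correlations to simulate at.
#' @param n_reps Simulated experiments per correlation.
#' @param n_boot Bootstrap iterations per experiment.
#' @param seed Optional integer seed for the whole sweep.
#' @param n_units,n_per_cell,noise_sd Generator settings
#'   (defaults: 15 sentence types, 13 ratings per cell, noise sd 1).
#' @param alpha Rejection threshold.
#' @param ... Further arguments to [sta_test()].
#' @return A tibble of class `power_curve`: `rho`, `n_reps`,
#'   `rejection_rate`, and a `p_values` list-column.
#' @export
power_curve <- function(rho_grid, n_reps = 35, n_boot = 1000, seed = NULL,
                        n_units = 15, n_per_cell = 13, noise_sd = 1,
                        alpha = 0.05, ...) {
  if (length(rho_grid) == 0) {
    abort("rho_grid must be nonempty", class = "statrace_domain_error")
  }
  if (n_reps < 1) abort("n_reps must be >= 1", class = "statrace_domain_error")
  local_seed_if(seed)
  rows <- purrr::map(rho_grid, function(rho) {
    p_values <- vapply(seq_len(n_reps), function(r) {
      lat <- sample_latents(n_units, rho)
      recs <- sample_ratings(lat, n_per_cell = n_per_cell,
                             noise_sd = noise_sd)
      suppressWarnings(
        sta_test(recs, n_boot = n_boot, ...)$p_value
      )
    }, 0)
    tibble::tibble(rho = rho, n_reps = as.integer(n_reps),
                   rejection_rate = mean(p_values < alpha),
                   p_values = list(p_values))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_curve", class(out))
  attr(out, "alpha") <- alpha
  out
}
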