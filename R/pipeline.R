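#' Run the full analysis pipeline
#'
#' Orchestrates every stage in order -- read or simulate, participant
#' exclusions, descriptive summaries, state-trace points, and the bootstrap
#' dimensionality test -- writing each stage's outputs and a manifest
#' (package version, seed, config hash, per-stage record counts) to the
#' output directory. All randomness flows from the single `seed`, so a
#' rerun with the same config is byte-identical.
#'
#' @param config A named list, or path to a JSON file encoding one, with
#'   elements: exactly one of `input` (list with `ratings` and
#'   `participants` CSV paths, plus optional `discrete`) or `simulation`
#'   (arguments to [sim_config()]); optional `fast_s` (exclusion threshold,
#'   default 240), `unit`, `weight_scheme`, `scheme`, `n_boot`
#'   (default 1000), `seed`, `alpha` (default 0.05).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the filtered tables, the exclusion
#'   report, the summary tables, and the `sta_result`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("stage config: file not found: ", config),
            class = "statrace_stage_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    abort("stage config: supply exactly one of input / simulation",
          class = "statrace_stage_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)),
            class = "statrace_stage_error")
    })
  }

  data <- stage("read/simulate", {
    if (has_input) {
      list(
        ratings = read_ratings(config$input$ratings,
                               discrete = config$input$discrete %||% TRUE),
        participants = read_participants(config$input$participants)
      )
    } else {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% seed
      generate_experiment(do.call(sim_config, sim_args))
    }
  })
  n_raw <- nrow(data$ratings)

  excl <- stage("exclusions", {
    apply_exclusions(data$ratings, data$participants,
                     fast_s = config$fast_s %||% 240)
  })
  write_ratings(excl$ratings, file.path(out_dir, "ratings_filtered.csv"))
  write_participants(excl$participants,
                     file.path(out_dir, "participants_filtered.csv"))
  write_json_file(glance(excl$report),
                  file.path(out_dir, "exclusion_report.json"))

  unit <- config$unit %||% "sentence_type_variant"
  summ <- stage("summaries", {
    cells <- aggregate_cells(excl$ratings, unit)
    diffs <- difference_distributions(excl$ratings)
    list(
      cells = cells,
      contrasts = contrast_table(excl$ratings,
                                 alpha = config$alpha %||% 0.05),
      extremity = extremity_proportions(excl$ratings),
      rt = suppressWarnings(rt_contrast(excl$ratings)),
      diffs = diffs,
      diff_groups = difference_summary(diffs)
    )
  })
  readr::write_csv(summ$cells, file.path(out_dir, "cell_summaries.csv"),
                   progress = FALSE)
  readr::write_csv(summ$contrasts, file.path(out_dir, "contrast_table.csv"),
                   progress = FALSE)
  readr::write_csv(summ$extremity, file.path(out_dir, "extremity.csv"),
                   progress = FALSE)
  write_json_file(list(means = summ$rt$means, test = summ$rt$test),
                  file.path(out_dir, "rt_contrast.json"))
  readr::write_csv(summ$diffs, file.path(out_dir, "differences.csv"),
                   progress = FALSE)

  sta <- stage("state trace", {
    suppressWarnings(sta_test(
      excl$ratings, unit = unit,
      n_boot = config$n_boot %||% 1000,
      seed = seed,
      scheme = config$scheme %||% "data_informed",
      weight_scheme = config$weight_scheme %||% "n"
    ))
  })
  readr::write_csv(tidy(sta), file.path(out_dir, "state_trace_points.csv"),
                   progress = FALSE)
  write_json_file(c(
    as.list(glance(sta)),
    list(seed = seed, boot_statistics = sta$boot_statistics)
  ), file.path(out_dir, "sta_result.json"))

  manifest <- list(
    package = "statrace",
    version = as.character(utils::packageVersion("statrace")),
    seed = seed,
    config_hash = rlang::hash(config),
    counts = list(
      records_raw = n_raw,
      records_filtered = nrow(excl$ratings),
      participants_recruited = excl$report$n_recruited,
      participants_retained = excl$report$n_retained,
      n_cells = nrow(summ$cells),
      n_units = nrow(sta$points)
    ),
    p_value = sta$p_value
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(data = excl, report = excl$report, summaries = summ,
                 sta = sta, out_dir = out_dir))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render the pipeline's figures
#'
#' Reads a [run_pipeline()] output directory and writes four figures:
#' per-condition rating histograms, the condition-mean dot plot with
#' confidence intervals, per-item difference violins, and the state-trace
#' scatter with the fitted monotone trace overlaid (drawn from the fitted
#' values the pipeline exported, so the overlay is nondecreasing in the
#' fitted order). Empty inputs skip the affected figure with a warning.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @param format `"pdf"` (default) or `"png"`.
#' @return Character vector of the figure paths written.
#' @export
make_plots <- function(out_dir, format = c("pdf", "png")) {
  format <- match.arg(format)
  need <- c("ratings_filtered.csv", "contrast_table.csv",
            "differences.csv", "state_trace_points.csv",
            "sta_result.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing) > 0) {
    abort(paste0("missing pipeline output(s): ",
                 paste(missing, collapse = ", ")),
          class = "statrace_io_error")
  }
  written <- character()
  save_fig <- function(plot, name) {
    path <- file.path(out_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, plot, width = 7, height = 5, device = format)
    written <<- c(written, path)
  }

  ratings <- read_ratings(file.path(out_dir, "ratings_filtered.csv"),
                          discrete = FALSE)
  if (nrow(ratings) > 0) {
    save_fig(plot_rating_histograms(ratings), "rating_histograms")
  } else {
    warn("no ratings: histogram skipped")
  }

  contrasts <- readr::read_csv(file.path(out_dir, "contrast_table.csv"),
                               show_col_types = FALSE, progress = FALSE)
  if (nrow(contrasts) > 0) {
    class(contrasts) <- c("contrast_table", class(contrasts))
    save_fig(autoplot(contrasts), "contrast_means")
  } else {
    warn("no contrasts: mean-CI plot skipped")
  }

  diffs <- readr::read_csv(file.path(out_dir, "differences.csv"),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(diffs) > 0) {
    save_fig(plot_difference_violins(diffs), "difference_violins")
  } else {
    warn("no differences: violin plot skipped")
  }

  td <- readr::read_csv(file.path(out_dir, "state_trace_points.csv"),
                        show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(out_dir, "sta_result.json"),
                              simplifyVector = TRUE)
  if (nrow(td) > 0) {
    trace <- td[order(td$position), ]
    p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_path(
        data = trace,
        ggplot2::aes(x = .data$fitted_x, y = .data$fitted_y),
        colour = "steelblue") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(
        x = "mean acceptability rating",
        y = "mean grammaticality rating",
        title = sprintf("State trace (statistic %.3g, p = %.2g)",
                        meta$observed_statistic, meta$p_value)) +
      ggplot2::theme_minimal()
    save_fig(p, "state_trace")
  } else {
    warn("no state-trace points: trace plot skipped")
  }
  written
}
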