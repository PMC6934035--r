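#' Welch's two-sample t test on rating vectors
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a two-sided p value, the default test family for condition contrasts
#' here (configurable to the pooled-variance test). When both groups are
#' constant the test is undefined: equal means return the `t = 0`, `p = 1`
#' convention, unequal means are an error rather than an infinite statistic.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (Student) test instead of Welch.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations",
          class = "statrace_domain_error")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1))
    }
    abort("both groups constant with unequal means: t undefined",
          class = "statrace_domain_error")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = pooled)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = fit$p.value)
}

#' Condition contrasts per sentence type
#'
#' For every sentence-type x variant combination, the mean rating under each
#' instruction condition, normal-approximation 95% confidence half-widths
#' (1.96 standard errors), and a response-level test of the
#' acceptability-vs-grammaticality difference. Rows whose p value is at or
#' above `alpha` carry the label `"No difference"`, the convention used
#' when such contrast tables are rendered.
#'
#' @param records Filtered (post-exclusion) rating records.
#' @param alpha Significance level for the `significant` flag.
#' @param pooled Passed to [welch_t()].
#' @return A tibble of class `contrast_table`: `sentence_type`, `variant`,
#'   `mean_acceptability`, `ci_acceptability`, `mean_grammaticality`,
#'   `ci_grammaticality`, `t_statistic`, `df`, `p_value`, `significant`,
#'   `label`. Variants observed in only one condition keep their means but
#'   have the test skipped (`NA` statistics).
#' @export
contrast_table <- function(records, alpha = 0.05, pooled = FALSE) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  one_group <- function(df) {
    a <- df$rating[df$condition == "acceptability"]
    g <- df$rating[df$condition == "grammaticality"]
    ci <- function(v) if (length(v) > 1) 1.96 * sd(v) / sqrt(length(v)) else NA_real_
    test <- if (length(a) >= 2 && length(g) >= 2) {
      welch_t(a, g, pooled = pooled)
    } else {
      tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    tibble::tibble(
      mean_acceptability = if (length(a)) mean(a) else NA_real_,
      ci_acceptability = ci(a),
      mean_grammaticality = if (length(g)) mean(g) else NA_real_,
      ci_grammaticality = ci(g),
      t_statistic = test$t, df = test$df, p_value = test$p
    )
  }
  out <- records |>
    dplyr::group_by(.data$sentence_type, .data$variant) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = !is.na(.data$p_value) & .data$p_value < alpha,
      label = dplyr::case_when(
        is.na(.data$p_value) ~ "Not tested",
        .data$p_value >= alpha ~ "No difference",
        TRUE ~ sprintf("t_df=%.0f = %.2g, p = %.2g", .data$df,
                       .data$t_statistic, .data$p_value)
      )
    )
  class(out) <- c("contrast_table", class(out))
  out
}

#' Proportion of responses at the scale endpoints
#'
#' How often did participants use the most extreme options in either
#' direction (ratings 0 or 5), reported separately per instruction
#' condition? A marker of the more categorical response style that
#' grammaticality instructions tend to elicit.
#'
#' @param records Rating records (attention checks are dropped).
#' @return Tibble with `condition`, `n`, `n_extreme`, `pct_extreme`
#'   (a percentage). Conditions with no responses are reported with `NA`.
#' @export
extremity_proportions <- function(records) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  base <- tibble::tibble(condition = rating_conditions)
  got <- records |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_extreme = sum(.data$rating %in% c(0, 5)),
      .groups = "drop"
    )
  base |>
    dplyr::left_join(got, by = "condition") |>
    dplyr::mutate(pct_extreme = 100 * .data$n_extreme / .data$n)
}

#' Standardized response-time contrast between conditions
#'
#' Response times are z-scored within participant (each participant's
#' trials get mean 0, sd 1 across both conditions), removing individual
#' speed differences; the two conditions' z-scores are then compared with
#' [welch_t()]. A participant whose response times have zero spread
#' contributes z-scores of 0, with a warning.
#'
#' @param records Rating records (attention checks are dropped).
#' @return A list: `means` (tibble of per-condition mean z-scores) and
#'   `test` (the [welch_t()] row).
#' @export
rt_contrast <- function(records) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  z <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      rt_z = if (sd(.data$rt_ms) > 0) {
        (.data$rt_ms - mean(.data$rt_ms)) / sd(.data$rt_ms)
      } else 0
    ) |>
    dplyr::ungroup()
  if (any(tapply(records$rt_ms, records$participant_id, sd) == 0)) {
    warn("participant(s) with zero response-time spread: z-scores set to 0")
  }
  means <- z |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_z = mean(.data$rt_z), .groups = "drop")
  a <- z$rt_z[z$condition == "acceptability"]
  g <- z$rt_z[z$condition == "grammaticality"]
  test <- if (length(a) >= 2 && length(g) >= 2 &&
                (var(a) > 0 || var(g) > 0)) {
    welch_t(a, g)
  } else {
    tibble::tibble(t = 0, df = NA_real_, p = 1)
  }
  list(means = means, test = test)
}

#' Per-item rating differences between instruction conditions
#'
#' For each item rated under both conditions, the difference of its mean
#' ratings, always acceptability minus grammaticality (so items rated more
#' leniently under grammaticality instructions are negative). The per-item
#' differences, grouped by sentence type x variant, are the raw material of
#' violin-style difference plots; their group spread makes claims about
#' differential variability checkable.
#'
#' @param records Rating records.
#' @return Tibble with one row per item: `sentence_type`, `variant`,
#'   `item_id`, `diff`. Items missing a condition are omitted; their count
#'   is in attribute `n_omitted`. See [difference_summary()] for group
#'   spread statistics.
#' @export
difference_distributions <- function(records) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  by_item <- records |>
    dplyr::group_by(.data$sentence_type, .data$variant, .data$item_id,
                    .data$condition) |>
    dplyr::summarise(m = mean(.data$rating), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  for (cond in rating_conditions) {
    if (!cond %in% names(by_item)) by_item[[cond]] <- NA_real_
  }
  omit <- is.na(by_item$acceptability) | is.na(by_item$grammaticality)
  out <- by_item[!omit, ] |>
    dplyr::mutate(diff = .data$acceptability - .data$grammaticality) |>
    dplyr::select("sentence_type", "variant", "item_id", "diff")
  attr(out, "n_omitted") <- sum(omit)
  out
}

#' @param diffs Output of [difference_distributions()].
#' @rdname difference_distributions
#' @return `difference_summary()` returns one row per sentence type x
#'   variant with the mean, sd, and quartiles of the per-item differences.
#' @export
difference_summary <- function(diffs) {
  diffs |>
    dplyr::group_by(.data$sentence_type, .data$variant) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      mean_diff = mean(.data$diff),
      sd_diff = if (dplyr::n() > 1) sd(.data$diff) else NA_real_,
      q25 = unname(quantile(.data$diff, 0.25)),
      median = unname(quantile(.data$diff, 0.5)),
      q75 = unname(quantile(.data$diff, 0.75)),
      .groups = "drop"
    )
}
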