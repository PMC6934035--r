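#' Did a participant pass the attention checks?
#'
#' The grammaticality block carries two fixed check items of known status:
#' "Him would have been fired." (ungrammatical) must receive one of the two
#' lowest response options (0 or 1), and "Sarah expected to get a good
#' grade." (grammatical) one of the two highest (4 or 5).
#'
#' @param records Rating records for a single participant, including the
#'   attention-check rows (`is_attention_check == TRUE`, `variant` `"low"`
#'   or `"high"`).
#' @return `TRUE`, `FALSE`, or `NA` when either check record is missing
#'   (treated as incomplete participation, not an attention failure).
#' @export
attention_check_pass <- function(records) {
  checks <- dplyr::filter(tibble::as_tibble(records), .data$is_attention_check)
  low <- checks$rating[checks$variant == "low"]
  high <- checks$rating[checks$variant == "high"]
  if (length(low) != 1 || length(high) != 1) return(NA)
  low %in% c(0, 1) && high %in% c(4, 5)
}

# round half away from zero, the convention behind printed whole percents
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct an exclusion report from counts
#'
#' Assembles the bookkeeping record of an exclusion stage: per-criterion
#' marginal counts, the number of participants triggering more than one
#' criterion, unique exclusions, retained participants, and the retention
#' percentage (rounded half away from zero to a whole percent). Checks the
#' arithmetic identities that must hold between them.
#'
#' @param n_recruited,n_non_native,n_incomplete,n_fast,n_attention_fail
#'   Marginal counts.
#' @param n_multiple_criteria Participants triggering two or more criteria.
#' @param n_excluded_unique Distinct excluded participants.
#' @return A list of class `exclusion_report`.
#' @examples
#' # the arithmetic of a typical crowd-sourced rating study
#' exclusion_report(n_recruited = 324, n_non_native = 5, n_incomplete = 26,
#'                  n_fast = 61, n_attention_fail = 108,
#'                  n_multiple_criteria = 55, n_excluded_unique = 135)
#' @export
exclusion_report <- function(n_recruited, n_non_native = 0, n_incomplete = 0,
                             n_fast = 0, n_attention_fail = 0,
                             n_multiple_criteria = 0,
                             n_excluded_unique = NULL) {
  marginal_sum <- n_non_native + n_incomplete + n_fast + n_attention_fail
  if (is.null(n_excluded_unique)) n_excluded_unique <- marginal_sum
  if (n_excluded_unique > marginal_sum) {
    abort("unique exclusions exceed the sum of criterion counts",
          class = "statrace_validation_error")
  }
  n_retained <- n_recruited - n_excluded_unique
  if (n_retained < 0) {
    abort("more exclusions than recruited participants",
          class = "statrace_validation_error")
  }
  structure(list(
    n_recruited = as.integer(n_recruited),
    n_non_native = as.integer(n_non_native),
    n_incomplete = as.integer(n_incomplete),
    n_fast = as.integer(n_fast),
    n_attention_fail = as.integer(n_attention_fail),
    n_multiple_criteria = as.integer(n_multiple_criteria),
    n_excluded_unique = as.integer(n_excluded_unique),
    n_retained = as.integer(n_retained),
    retention_pct = if (n_recruited > 0) {
      as.integer(round_half_up(100 * n_retained / n_recruited))
    } else NA_integer_
  ), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  recruited: %d, retained: %d (%s%% retention)\n",
              x$n_recruited, x$n_retained,
              ifelse(is.na(x$retention_pct), "-", x$retention_pct)))
  cat(sprintf(
    "  non-native %d | incomplete %d | fast %d | attention-fail %d\n",
    x$n_non_native, x$n_incomplete, x$n_fast, x$n_attention_fail))
  cat(sprintf("  multiple criteria: %d, unique exclusions: %d\n",
              x$n_multiple_criteria, x$n_excluded_unique))
  invisible(x)
}

#' @method tidy exclusion_report
#' @export
tidy.exclusion_report <- function(x, ...) {
  tibble::tibble(
    criterion = c("non_native", "incomplete", "fast", "attention_fail"),
    n = c(x$n_non_native, x$n_incomplete, x$n_fast, x$n_attention_fail)
  )
}

#' @method glance exclusion_report
#' @export
glance.exclusion_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Apply the study's participant-exclusion rules
#'
#' A participant is excluded if any of the following hold: they reported
#' being a non-native English speaker; they did not complete all questions
#' (including missing an attention-check record); their total participation
#' time was unrealistically fast (below `fast_s` seconds, default 240 --
#' four minutes); or they failed the attention checks
#' ([attention_check_pass()]). The filtered tables keep only retained
#' participants' non-attention trials.
#'
#' @param ratings Trial records (standard schema).
#' @param participants Participant metadata (standard schema).
#' @param fast_s Fast-completion threshold in seconds.
#' @return A list: `ratings` and `participants` (filtered tibbles) and
#'   `report` (an [exclusion_report()]).
#' @export
apply_exclusions <- function(ratings, participants, fast_s = 240) {
  ratings <- tibble::as_tibble(ratings)
  participants <- tibble::as_tibble(participants)
  if (nrow(participants) == 0) {
    return(list(ratings = ratings[0, ], participants = participants,
                report = exclusion_report(0)))
  }
  if (nrow(ratings) > 0) {
    pass <- ratings |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_map(~ attention_check_pass(.x)) |>
      unlist()
    names(pass) <- sort(unique(ratings$participant_id))
    attn <- unname(pass[participants$participant_id])
  } else {
    attn <- rep(NA, nrow(participants))
  }

  non_native <- !participants$native_english
  # a missing attention-check record counts as not completing all questions
  incomplete <- !participants$completed |
    is.na(attn) |
    !participants$participant_id %in% ratings$participant_id
  fast <- participants$total_time_s < fast_s
  attention_fail <- !is.na(attn) & !attn

  n_crit <- non_native + incomplete + fast + attention_fail
  excluded <- n_crit > 0
  report <- exclusion_report(
    n_recruited = nrow(participants),
    n_non_native = sum(non_native),
    n_incomplete = sum(incomplete),
    n_fast = sum(fast),
    n_attention_fail = sum(attention_fail),
    n_multiple_criteria = sum(n_crit >= 2),
    n_excluded_unique = sum(excluded)
  )
  keep <- participants$participant_id[!excluded]
  list(
    ratings = dplyr::filter(ratings, .data$participant_id %in% keep,
                            !.data$is_attention_check),
    participants = dplyr::filter(participants,
                                 .data$participant_id %in% .env$keep),
    report = report
  )
}
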