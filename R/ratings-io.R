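#' Read a trial-level ratings table
#'
#' Reads the package's ratings CSV schema: one row per trial, recording which
#' participant rated which item, under which instruction condition
#' (`acceptability` or `grammaticality`), the 0--5 response, the response
#' time in milliseconds, the block the trial belonged to, and whether the
#' item was an attention check.
#'
#' @param path Path to a CSV file with columns `participant_id`, `item_id`,
#'   `sentence_type`, `variant`, `condition`, `rating`, `rt_ms`,
#'   `block_index`, `is_attention_check` (in any order; all required).
#' @param discrete If `TRUE` (default), ratings must be integers in 0--5,
#'   the coding used on the six-point response scale. Set to `FALSE` for
#'   simulated data whose ratings are continuous (and may fall outside the
#'   scale when the simulator's noise is not clipped).
#' @return A tibble of rating records in the documented column order.
#' @seealso [write_ratings()], [aggregate_cells()]
#' @export
read_ratings <- function(path, discrete = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("ratings file not found: ", path), class = "statrace_io_error")
  }
  check_header(path, ratings_cols, "ratings")
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      item_id = readr::col_character(),
      sentence_type = readr::col_character(),
      variant = readr::col_character(),
      condition = readr::col_character(),
      rating = readr::col_double(),
      rt_ms = readr::col_double(),
      block_index = readr::col_integer(),
      is_attention_check = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(ratings_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("ratings CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "statrace_schema_error")
  }
  df <- df[ratings_cols]
  validate_ratings(df, discrete = discrete)
  df
}

#' Write a trial-level ratings table
#'
#' Writes the documented ratings CSV (comma-separated, UTF-8, header row,
#' fixed column order). `read_ratings(write_ratings(x, p))` reproduces `x`
#' exactly for integer-coded ratings; continuous simulated ratings
#' round-trip to the precision of decimal text formatting.
#'
#' @param records Tibble of rating records (see [read_ratings()] for the
#'   schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(records, path) {
  records <- tibble::as_tibble(records)[ratings_cols]
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and write participant metadata
#'
#' Participant self-report and session metadata: age, gender, whether the
#' participant reported being a native English speaker, whether they
#' completed all questions, and total participation time in seconds. These
#' fields feed the exclusion stage ([apply_exclusions()]).
#'
#' @param path CSV path with columns `participant_id`, `age`, `gender`,
#'   `native_english`, `completed`, `total_time_s`.
#' @return `read_participants()` returns a tibble; `write_participants()`
#'   returns `path` invisibly.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("participants file not found: ", path),
          class = "statrace_io_error")
  }
  check_header(path, participants_cols, "participants")
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age = readr::col_double(),
      gender = readr::col_character(),
      native_english = readr::col_logical(),
      completed = readr::col_logical(),
      total_time_s = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(participants_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("participants CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "statrace_schema_error")
  }
  df <- df[participants_cols]
  if (anyDuplicated(df$participant_id) > 0) {
    abort("duplicated participant_id in participants table",
          class = "statrace_validation_error")
  }
  bad <- which(!is.na(df$total_time_s) & df$total_time_s < 0)
  if (length(bad) > 0) {
    abort(paste0("negative total_time_s at row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "statrace_validation_error")
  }
  df
}

#' @param participants Tibble of participant records.
#' @rdname read_participants
#' @export
write_participants <- function(participants, path) {
  participants <- tibble::as_tibble(participants)[participants_cols]
  readr::write_csv(participants, path, progress = FALSE)
  invisible(path)
}

check_header <- function(path, expected, what) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE, progress = FALSE))
  missing <- setdiff(expected, hdr)
  if (length(missing) > 0) {
    abort(paste0(what, " CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "statrace_schema_error")
  }
  invisible(hdr)
}

# Validates trial records against the schema invariants; row numbers in
# error messages refer to data rows (header excluded).
validate_ratings <- function(df, discrete = TRUE) {
  if (nrow(df) == 0) return(invisible(df))
  if (discrete) {
    bad <- which(is.na(df$rating) | df$rating %% 1 != 0 |
                   df$rating < 0 | df$rating > 5)
    if (length(bad) > 0) {
      abort(paste0("rating outside the 0-5 integer scale at row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "statrace_validation_error")
    }
  }
  bad_rt <- which(!is.na(df$rt_ms) & df$rt_ms < 0)
  if (length(bad_rt) > 0) {
    abort(paste0("negative rt_ms at row(s) ",
                 paste(head(bad_rt, 5), collapse = ", ")),
          class = "statrace_validation_error")
  }
  bad_cond <- which(!df$condition %in% rating_conditions)
  if (length(bad_cond) > 0) {
    abort(paste0("unknown condition at row(s) ",
                 paste(head(bad_cond, 5), collapse = ", "),
                 " (expected acceptability/grammaticality)"),
          class = "statrace_validation_error")
  }
  dup <- duplicated(df[c("participant_id", "item_id")])
  if (any(dup)) {
    abort(paste0("item rated twice by the same participant at row(s) ",
                 paste(head(which(dup), 5), collapse = ", ")),
          class = "statrace_validation_error")
  }
  invisible(df)
}
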