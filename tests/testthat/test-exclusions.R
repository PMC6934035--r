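make_participant_records <- function(pid, low = 0, high = 5,
                                     drop = character()) {
  rows <- tibble::tibble(
    participant_id = pid,
    item_id = c("attn_low", "attn_high"),
    sentence_type = "attention_check",
    variant = c("low", "high"),
    condition = "grammaticality",
    rating = c(low, high),
    rt_ms = 5000, block_index = 1L,
    is_attention_check = TRUE
  )
  rows[!rows$variant %in% drop, ]
}

test_that("attention rule: low item in {0,1} and high item in {4,5}", {
  # full boundary enumeration of the pass rule
  for (low in 0:5) {
    for (high in 0:5) {
      expect_identical(
        attention_check_pass(make_participant_records("p", low, high)),
        low %in% c(0, 1) && high %in% c(4, 5)
      )
    }
  }
  expect_identical(attention_check_pass(
    make_participant_records("p", drop = "low")), NA)
})

test_that("report arithmetic reproduces the printed study counts", {
  rep <- exclusion_report(
    n_recruited = 324, n_non_native = 5, n_incomplete = 26, n_fast = 61,
    n_attention_fail = 108, n_multiple_criteria = 55,
    n_excluded_unique = 135
  )
  expect_identical(rep$n_retained, 189L)
  expect_identical(rep$retention_pct, 58L)
  expect_identical(rep$n_excluded_unique + rep$n_retained, rep$n_recruited)
  expect_error(exclusion_report(10, n_non_native = 2, n_excluded_unique = 5),
               class = "statrace_validation_error")
})

test_that("an 8-participant planted fixture is counted exactly", {
  pids <- sprintf("q%d", 1:8)
  participants <- tibble::tibble(
    participant_id = pids, age = 30, gender = "female",
    native_english = TRUE, completed = TRUE, total_time_s = 600
  )
  ratings <- dplyr::bind_rows(lapply(pids, make_participant_records))
  # plant: non-native, incomplete, fast(180 s), attention-fail,
  # fast + attention-fail; q6..q8 clean
  participants$native_english[1] <- FALSE
  participants$completed[2] <- FALSE
  participants$total_time_s[3] <- 180
  ratings$rating[ratings$participant_id == "q4" &
                   ratings$variant == "low"] <- 3
  participants$total_time_s[5] <- 180
  ratings$rating[ratings$participant_id == "q5" &
                   ratings$variant == "low"] <- 3

  res <- apply_exclusions(ratings, participants)
  expect_identical(res$report$n_non_native, 1L)
  expect_identical(res$report$n_incomplete, 1L)
  expect_identical(res$report$n_fast, 2L)
  expect_identical(res$report$n_attention_fail, 2L)
  expect_identical(res$report$n_multiple_criteria, 1L)
  expect_identical(res$report$n_excluded_unique, 5L)
  expect_identical(res$report$n_retained, 3L)
  expect_identical(sort(res$participants$participant_id),
                   c("q6", "q7", "q8"))
})

test_that("clean participants are all retained and exclusion is idempotent", {
  pids <- sprintf("r%02d", 1:10)
  participants <- tibble::tibble(
    participant_id = pids, age = 25, gender = "male",
    native_english = TRUE, completed = TRUE, total_time_s = 500
  )
  ratings <- dplyr::bind_rows(lapply(pids, make_participant_records))
  res <- apply_exclusions(ratings, participants)
  expect_identical(res$report$retention_pct, 100L)
  expect_identical(res$report$n_excluded_unique, 0L)

  # filtered output excludes attention rows; add passing checks back to
  # verify nobody else is removed on a second pass
  again <- apply_exclusions(
    dplyr::bind_rows(res$ratings,
                     dplyr::bind_rows(lapply(pids, make_participant_records))),
    res$participants)
  expect_identical(again$report$n_excluded_unique, 0L)
  expect_identical(again$participants, res$participants)
})

test_that("partition and overlap-bound invariants hold on random fixtures", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 12
    pids <- sprintf("s%02d", seq_len(n))
    participants <- tibble::tibble(
      participant_id = pids, age = 30, gender = "x",
      native_english = runif(n) > 0.2, completed = runif(n) > 0.2,
      total_time_s = sample(c(180, 600), n, replace = TRUE)
    )
    ratings <- dplyr::bind_rows(lapply(pids, function(p) {
      make_participant_records(p, low = sample(0:5, 1),
                               high = sample(0:5, 1))
    }))
    res <- apply_exclusions(ratings, participants)
    r <- res$report
    expect_identical(r$n_excluded_unique + r$n_retained, r$n_recruited)
    expect_lte(r$n_excluded_unique,
               r$n_non_native + r$n_incomplete + r$n_fast +
                 r$n_attention_fail)
    expect_gte(r$n_excluded_unique,
               max(r$n_non_native, r$n_incomplete, r$n_fast,
                   r$n_attention_fail))
    expect_identical(r$retention_pct,
                     as.integer(floor(100 * r$n_retained /
                                        r$n_recruited + 0.5)))
  }
})

test_that("empty input yields an all-zero report", {
  no_participants <- tibble::tibble(
    participant_id = character(), age = double(), gender = character(),
    native_english = logical(), completed = logical(),
    total_time_s = double()
  )
  res <- apply_exclusions(random_records(seed = 1)[0, ], no_participants)
  expect_identical(res$report$n_recruited, 0L)
  expect_identical(res$report$n_excluded_unique, 0L)
})
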