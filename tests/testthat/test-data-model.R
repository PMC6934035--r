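test_that("ratings CSV round-trips exactly for integer-coded records", {
  withr::with_tempfile("f", {
    for (s in 1:100) {
      recs <- random_records(seed = s)
      write_ratings(recs, f)
      back <- read_ratings(f)
      expect_identical(as.data.frame(back), as.data.frame(recs))
    }
  })
})

test_that("continuous simulated ratings round-trip to text precision", {
  withr::with_tempfile("f", {
    recs <- sample_ratings(sample_latents(5, 0.9, seed = 1), seed = 2)
    write_ratings(recs, f)
    back <- read_ratings(f, discrete = FALSE)
    expect_equal(back$rating, recs$rating, tolerance = 1e-12)
  })
})

test_that("schema and validation errors name the problem", {
  withr::with_tempfile("f", {
    writeLines("participant_id,item_id\np1,i1", f)
    expect_error(read_ratings(f), class = "statrace_schema_error")

    recs <- random_records(seed = 1)
    recs$rating[2] <- 7
    write_ratings(recs, f)
    expect_error(read_ratings(f), "row\\(s\\) 2",
                 class = "statrace_validation_error")

    recs <- random_records(seed = 1)
    recs$item_id[2] <- recs$item_id[1]
    recs$participant_id[2] <- recs$participant_id[1]
    write_ratings(recs, f)
    expect_error(read_ratings(f), "twice",
                 class = "statrace_validation_error")
  })
})

test_that("empty record sets write a header-only file", {
  withr::with_tempfile("f", {
    write_ratings(random_records(seed = 1)[0, ], f)
    expect_length(readLines(f), 1)
    expect_identical(nrow(read_ratings(f)), 0L)
  })
})

test_that("participant metadata round-trips and rejects duplicates", {
  withr::with_tempfile("f", {
    part <- tibble::tibble(
      participant_id = c("p1", "p2"), age = c(30, 40),
      gender = c("female", "male"), native_english = c(TRUE, FALSE),
      completed = TRUE, total_time_s = c(600, 700)
    )
    write_participants(part, f)
    expect_identical(as.data.frame(read_participants(f)),
                     as.data.frame(part))
    part$participant_id[2] <- "p1"
    write_participants(part, f)
    expect_error(read_participants(f), class = "statrace_validation_error")
  })
})

test_that("cell aggregation computes mean, count and sample variance", {
  one <- random_records(seed = 3)[1, ]
  one$rating <- 4
  cells <- aggregate_cells(one)
  expect_equal(cells$mean, 4)
  expect_equal(cells$n, 1L)
  expect_equal(cells$variance, 0)

  two <- one[c(1, 1), ]
  two$participant_id <- c("a", "b")
  two$rating <- c(2, 4)
  cells <- aggregate_cells(two)
  expect_equal(cells$mean, 3)
  expect_equal(cells$n, 2L)
  expect_equal(cells$variance, 2)

  expect_identical(nrow(aggregate_cells(two[0, ])), 0L)
})

test_that("aggregation conserves counts and pools to the grand mean", {
  for (s in 1:20) {
    recs <- random_records(n_participants = 6, n_items = 8, seed = s)
    for (unit in c("sentence_type_variant", "item")) {
      cells <- aggregate_cells(recs, unit)
      expect_identical(sum(cells$n), nrow(recs))
      expect_equal(sum(cells$mean * cells$n) / sum(cells$n),
                   mean(recs$rating), tolerance = 1e-12)
      expect_true(all(cells$mean >= 0 & cells$mean <= 5))
    }
  }
})

test_that("attention-check trials are excluded from cells", {
  recs <- random_records(seed = 5)
  attn <- recs[1, ]
  attn$participant_id <- "pX"
  attn$is_attention_check <- TRUE
  cells <- aggregate_cells(dplyr::bind_rows(recs, attn))
  expect_identical(sum(cells$n), nrow(recs))
})

test_that("state-trace points pair condition means and drop lone units", {
  recs <- monotone_records(n_units = 5)
  pts <- state_trace_points(aggregate_cells(recs))
  expect_identical(nrow(pts), 5L)
  expect_equal(pts$x, seq(0.5, 4.5, length.out = 5))
  expect_equal(pts$y, seq(1, 4, length.out = 5))
  expect_true(all(pts$wx > 0 & pts$wy > 0))

  lop <- dplyr::filter(recs, !(sentence_type == "type01" &
                                 condition == "grammaticality"))
  expect_warning(pts2 <- state_trace_points(aggregate_cells(lop)),
                 "missing one condition")
  expect_identical(nrow(pts2), 4L)
})
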