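test_that("welch t matches hand-computed values and conventions", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4.0, tolerance = 1e-9)

  res2 <- welch_t(c(0, 0, 1), c(5, 5, 4))
  expect_lt(res2$t, 0)
  expect_lt(res2$p, 0.05)

  same <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), class = "statrace_domain_error")
  expect_error(welch_t(1, c(1, 2)), class = "statrace_domain_error")
})

test_that("welch t is antisymmetric in its groups", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = 0.5)
    f <- welch_t(a, b); r <- welch_t(b, a)
    expect_equal(f$t, -r$t, tolerance = 1e-12)
    expect_equal(f$df, r$df, tolerance = 1e-12)
    expect_equal(f$p, r$p, tolerance = 1e-12)
  }
})

shifted_fixture <- function(shift_type = "type02", shift = 2, seed = 8) {
  lat <- tibble::tibble(
    unit_id = sprintf("type%02d", 1:4),
    u1 = c(1, 2, 3, 4), u2 = c(1, 2, 3, 4)
  )
  recs <- sample_ratings(lat, n_per_cell = 40, noise_sd = 0.3,
                         seed = seed)
  recs$rating[recs$sentence_type == shift_type &
                recs$condition == "acceptability"] <-
    recs$rating[recs$sentence_type == shift_type &
                  recs$condition == "acceptability"] + shift
  recs
}

test_that("contrast table flags exactly the shifted variant", {
  recs <- shifted_fixture()
  tab <- contrast_table(recs)
  hit <- tab[tab$significant, ]
  expect_identical(hit$sentence_type, "type02")
  expect_gt(hit$mean_acceptability - hit$mean_grammaticality, 1)
  expect_true(all(tab$label[!tab$significant] == "No difference"))

  # condition means agree with the aggregation path
  cells <- aggregate_cells(recs)
  acc <- cells$mean[cells$condition == "acceptability"]
  expect_equal(sort(tab$mean_acceptability), sort(acc),
               tolerance = 1e-12)
})

test_that("identical conditions yield a table of no differences", {
  lat <- tibble::tibble(unit_id = c("a", "b"), u1 = c(1, 3), u2 = c(1, 3))
  recs <- sample_ratings(lat, n_per_cell = 10, noise_sd = 0, seed = 1)
  tab <- contrast_table(recs)
  expect_true(all(tab$label == "No difference"))
})

test_that("extremity proportions count scale endpoints per condition", {
  recs <- random_records(seed = 2)
  recs$rating <- rep(c(2, 3), length.out = nrow(recs))
  ext <- extremity_proportions(recs)
  expect_equal(ext$pct_extreme[!is.na(ext$pct_extreme)],
               rep(0, sum(!is.na(ext$pct_extreme))))

  recs4 <- recs[1:4, ]
  recs4$participant_id <- sprintf("z%d", 1:4)
  recs4$condition <- "acceptability"
  recs4$rating <- c(0, 5, 2, 3)
  ext4 <- extremity_proportions(recs4)
  expect_equal(ext4$pct_extreme[ext4$condition == "acceptability"], 50)
  expect_true(is.na(ext4$pct_extreme[ext4$condition == "grammaticality"]))
})

test_that("response times standardize within participant", {
  recs <- random_records(n_participants = 6, seed = 12)
  recs$rt_ms <- recs$rt_ms +
    ifelse(recs$condition == "grammaticality", 2000, 0)
  res <- rt_contrast(recs)
  mg <- res$means$mean_z[res$means$condition == "grammaticality"]
  ma <- res$means$mean_z[res$means$condition == "acceptability"]
  expect_gt(mg, 0)
  expect_lt(ma, 0)

  # standardization contract: per-participant mean 0, sd 1
  z <- recs |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(rt_z = (rt_ms - mean(rt_ms)) / sd(rt_ms)) |>
    dplyr::summarise(m = mean(rt_z), s = sd(rt_z))
  expect_equal(z$m, rep(0, nrow(z)), tolerance = 1e-12)
  expect_equal(z$s, rep(1, nrow(z)), tolerance = 1e-12)

  flat <- recs
  flat$rt_ms <- 5000
  expect_warning(res0 <- rt_contrast(flat), "zero response-time spread")
  expect_equal(res0$means$mean_z, c(0, 0))
  expect_equal(res0$test$t, 0)
})

test_that("per-item differences carry the acceptability-minus sign", {
  recs <- shifted_fixture()
  diffs <- difference_distributions(recs)
  expect_true(all(diffs$diff[diffs$sentence_type == "type02"] > 0))

  # group means equal the difference of condition means per unit
  cells <- aggregate_cells(recs, unit = "item")
  grp <- difference_summary(diffs)
  for (k in seq_len(nrow(grp))) {
    items <- diffs$item_id[diffs$sentence_type == grp$sentence_type[k]]
    a <- cells$mean[cells$unit_id %in% items &
                      cells$condition == "acceptability"]
    g <- cells$mean[cells$unit_id %in% items &
                      cells$condition == "grammaticality"]
    expect_equal(grp$mean_diff[k], mean(a) - mean(g), tolerance = 1e-12)
  }

  # items missing a condition are omitted and counted
  lop <- dplyr::filter(recs, !(item_id == "type01" &
                                 condition == "grammaticality"))
  d2 <- difference_distributions(lop)
  expect_identical(attr(d2, "n_omitted"), 1L)
  expect_false("type01" %in% d2$item_id)
})

test_that("planted variance ratios are visible in group spreads", {
  lat <- tibble::tibble(unit_id = sprintf("t%d", 1:2),
                        u1 = c(2, 2), u2 = c(2, 2))
  recs <- dplyr::bind_rows(lapply(1:12, function(i) {
    r <- sample_ratings(lat, n_per_cell = 6, noise_sd = 0.1,
                        seed = 100 + i)
    r$item_id <- paste0(r$item_id, "_i", i)
    r
  }))
  # make t2's per-item acceptability means swing widely
  bump <- rep(c(-1.5, 1.5), 6)
  for (i in 1:12) {
    sel <- recs$sentence_type == "t2" &
      recs$item_id == paste0("t2_i", i) &
      recs$condition == "acceptability"
    recs$rating[sel] <- recs$rating[sel] + bump[i]
  }
  grp <- difference_summary(difference_distributions(recs))
  expect_gt(grp$sd_diff[grp$sentence_type == "t2"],
            3 * grp$sd_diff[grp$sentence_type == "t1"])
})
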