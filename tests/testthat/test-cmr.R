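test_that("PAVA reproduces hand-worked weighted pools", {
  f1 <- isotonic(c(1, 2, 3))
  expect_equal(f1$fitted, c(1, 2, 3))
  expect_equal(f1$sse, 0)

  f2 <- isotonic(c(1, 3, 2))
  expect_equal(f2$fitted, c(1, 2.5, 2.5))
  expect_equal(f2$sse, 0.5)

  f3 <- isotonic(c(3, 1), c(1, 3))
  expect_equal(f3$fitted, c(1.5, 1.5))
  expect_equal(f3$sse, 3.0)

  expect_error(isotonic(numeric(0)), class = "statrace_domain_error")
  expect_error(isotonic(1:3, c(1, -1, 1)), class = "statrace_domain_error")
})

test_that("PAVA agrees with the QP projection oracle", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    v <- rnorm(n, sd = 2)
    w <- runif(n, 0.1, 5)
    mine <- isotonic(v, w)
    qp <- qp_isotonic(v, w)
    expect_lt(abs(mine$sse - qp$sse), 1e-8)
    expect_equal(mine$fitted, qp$fitted, tolerance = 1e-5)
    expect_true(all(diff(mine$fitted) >= -1e-12))
  }
  # the plain-R PAVA used inside the brute-force CMR oracle is itself sound
  for (i in 1:20) {
    n <- sample(2:20, 1)
    v <- rnorm(n); w <- runif(n, 0.2, 3)
    expect_lt(abs(r_pava(v, w) - qp_isotonic(v, w)$sse), 1e-8)
  }
})

test_that("exact coupled fit matches enumeration on worked examples", {
  mono <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3))
  fit <- coupled_fit_exact(mono)
  expect_equal(fit$statistic, 0)
  expect_identical(fit$order, 1:3)

  cross <- tibble::tibble(x = c(0, 1), y = c(1, 0))
  expect_equal(coupled_fit_exact(cross)$fit_1d, 0.5)

  anti <- tibble::tibble(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  expect_equal(coupled_fit_exact(anti)$fit_1d, 5.0)

  big <- random_points(12, seed = 1)
  expect_error(coupled_fit_exact(big), class = "statrace_size_error")
})

test_that("exact fit equals the independent brute-force oracle", {
  for (s in 1:30) {
    n <- sample(3:6, 1)
    pts <- random_points(n, seed = 200 + s)
    expect_equal(coupled_fit_exact(pts)$fit_1d, brute_cmr(pts),
                 tolerance = 1e-9)
  }
})

test_that("heuristic reaches the exact optimum on small instances", {
  for (s in 1:100) {
    n <- sample(4:8, 1)
    pts <- random_points(n, seed = 400 + s)
    h <- coupled_fit_heuristic(pts, seed = s)
    e <- coupled_fit_exact(pts)
    expect_gte(h$fit_1d, e$fit_1d - 1e-12)
    expect_lt(h$fit_1d - e$fit_1d, 1e-9)
  }
})

test_that("heuristic skips the search for jointly monotone data", {
  pts <- tibble::tibble(x = 1:6 / 2, y = c(1, 1.5, 1.5, 2, 4, 4.5))
  h <- coupled_fit_heuristic(pts, seed = 1)
  expect_equal(h$statistic, 0)
  expect_identical(h$n_starts, 1L)  # the order-by-x start already fits
})

test_that("seeded heuristic runs are identical", {
  pts <- random_points(15, seed = 5)
  a <- coupled_fit_heuristic(pts, seed = 42)
  b <- coupled_fit_heuristic(pts, seed = 42)
  expect_identical(a$fit_1d, b$fit_1d)
  expect_identical(a$order, b$order)
})

test_that("fits are scale-equivariant and permutation-invariant", {
  pts <- random_points(7, seed = 77)
  base <- coupled_fit_exact(pts)$fit_1d
  for (c in c(0.5, 2, 10)) {
    scaled <- dplyr::mutate(pts, x = x * c, y = y * c)
    expect_equal(coupled_fit_exact(scaled)$fit_1d, c^2 * base,
                 tolerance = 1e-9)
  }
  set.seed(3)
  for (i in 1:5) {
    perm <- sample(nrow(pts))
    expect_equal(coupled_fit_exact(pts[perm, ])$fit_1d, base,
                 tolerance = 1e-12)
  }
})

test_that("zero statistic exactly characterizes a common monotone order", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    # integer grids produce frequent ties and genuine zero cases
    pts <- tibble::tibble(x = sample(0:3, n, TRUE), y = sample(0:3, n, TRUE))
    fit <- coupled_fit_exact(pts)
    P <- all_perms(n)
    common <- any(apply(P, 1, function(ord) {
      all(diff(pts$x[ord]) >= 0) && all(diff(pts$y[ord]) >= 0)
    }))
    expect_identical(fit$statistic == 0, common)
  }
})

test_that("two-dimensional fit is free without constraints, chained with", {
  pts <- random_points(6, seed = 6)
  expect_identical(fit_2d(pts), 0)

  # a chain equal to the order-by-x permutation reduces to one isotonic fit
  ord <- order(pts$x)
  chain <- data.frame(before = pts$unit_id[ord[-length(ord)]],
                      after = pts$unit_id[ord[-1]])
  expect_equal(fit_2d(pts, chain),
               isotonic(pts$y[ord], pts$wy[ord])$sse, tolerance = 1e-6)

  cyc <- data.frame(before = c("u01", "u02"), after = c("u02", "u01"))
  expect_error(fit_2d(pts, cyc), class = "statrace_domain_error")
})

test_that("tidy and glance expose the fit in tabular form", {
  pts <- random_points(5, seed = 9)
  fit <- coupled_fit_exact(pts)
  td <- tidy(fit)
  expect_identical(nrow(td), 5L)
  expect_setequal(td$position, 1:5)
  ord_fit <- td$fitted_x[order(td$position)]
  expect_true(all(diff(ord_fit) >= -1e-12))
  gl <- glance(fit)
  expect_identical(gl$method, "exact")
  expect_equal(gl$statistic, fit$statistic)
})
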