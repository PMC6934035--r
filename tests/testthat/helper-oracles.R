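# Independent oracles and fixture generators used across the suite.

# Isotonic regression as a quadratic-programming projection onto the cone
# of nondecreasing vectors: min sum w (v - f)^2 s.t. f[i] <= f[i+1].
# Independent of the package's pool-adjacent-violators path.
qp_isotonic <- function(v, w = rep(1, length(v))) {
  n <- length(v)
  if (n == 1) return(list(fitted = v, sse = 0))
  A <- cbind(diag(n - 1), 0) - cbind(0, diag(n - 1))
  sol <- pracma::quadprog(2 * diag(w), -2 * w * v, A = A, b = rep(0, n - 1))
  list(fitted = sol$xmin, sse = sum(w * (v - sol$xmin)^2))
}

# Plain-R weighted PAVA, written independently of the compiled core; used
# to make the brute-force permutation oracle affordable. Itself checked
# against qp_isotonic in the isotonic tests.
r_pava <- function(v, w = rep(1, length(v))) {
  n <- length(v)
  W <- S <- numeric(0)
  for (i in seq_len(n)) {
    W <- c(W, w[i]); S <- c(S, w[i] * v[i])
    k <- length(W)
    while (k > 1 && S[k - 1] / W[k - 1] > S[k] / W[k]) {
      W[k - 1] <- W[k - 1] + W[k]; S[k - 1] <- S[k - 1] + S[k]
      W <- W[-k]; S <- S[-k]
      k <- k - 1
    }
  }
  sum(w * v^2) - sum(S^2 / W)
}

# all permutations of 1..n, by insertion
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p + (p >= i)
    cbind(i, q, deparse.level = 0)
  }))
}

# Brute-force coupled-fit minimum over every unit order (R-only path).
brute_cmr <- function(pts) {
  P <- all_perms(nrow(pts))
  min(apply(P, 1, function(ord) {
    r_pava(pts$x[ord], pts$wx[ord]) + r_pava(pts$y[ord], pts$wy[ord])
  }))
}

random_points <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    unit_id = sprintf("u%02d", seq_len(n)),
    x = runif(n, 0, 5), y = runif(n, 0, 5),
    wx = runif(n, 0.5, 20), wy = runif(n, 0.5, 20)
  )
}

# Valid integer-coded trial records with unique (participant, item) pairs.
random_records <- function(n_participants = 4, n_items = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    item_id = sprintf("it%02d", seq_len(n_items)),
    stringsAsFactors = FALSE
  )
  keep <- grid[sample.int(nrow(grid), ceiling(nrow(grid) * 0.8)), ]
  type_of <- setNames(sprintf("type%02d", rep(1:3, length.out = n_items)),
                      sprintf("it%02d", seq_len(n_items)))
  tibble::tibble(
    participant_id = keep$participant_id,
    item_id = keep$item_id,
    sentence_type = unname(type_of[keep$item_id]),
    variant = "base",
    condition = sample(c("acceptability", "grammaticality"),
                       nrow(keep), replace = TRUE),
    rating = as.double(sample(0:5, nrow(keep), replace = TRUE)),
    rt_ms = as.double(sample(1000:9000, nrow(keep), replace = TRUE)),
    block_index = sample(0:1, nrow(keep), replace = TRUE),
    is_attention_check = FALSE
  )
}

# A noiseless, jointly monotone experiment: constant ratings within each
# cell, cell means strictly increasing in both conditions.
monotone_records <- function(n_units = 10, n_per_cell = 9) {
  lat <- tibble::tibble(
    unit_id = sprintf("type%02d", seq_len(n_units)),
    u1 = seq(0.5, 4.5, length.out = n_units),
    u2 = seq(1, 4, length.out = n_units)
  )
  sample_ratings(lat, n_per_cell = n_per_cell, noise_sd = 0)
}
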