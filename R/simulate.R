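#' Simulation settings for a synthetic rating experiment
#'
#' Bundles the generator's parameters. Defaults mirror the study design
#' being emulated: 15 sentence-type conditions, a 0--5 rating scale,
#' observation noise with standard deviation 1, about 13 ratings per cell,
#' and two 30-item blocks per participant.
#'
#' @param n_units Number of sentence-type conditions.
#' @param rho Target correlation between the two latent consensus means,
#'   in (0, 1].
#' @param latent_low,latent_high Bounds of the rating scale; type-1 latents
#'   are uniform on this interval.
#' @param noise_sd Standard deviation of the Gaussian observation noise
#'   added to each rating.
#' @param n_per_cell Ratings per unit per condition for [sample_ratings()].
#' @param n_participants Simulated participants for [generate_experiment()].
#'   The default 39 yields roughly 13 ratings per item per condition with
#'   the default item pool.
#' @param items_per_block Probe items per instruction block.
#' @param n_items_per_type Item pool size per sentence type; the pool must
#'   hold at least two blocks' worth of items.
#' @param discretize If `TRUE`, ratings are clipped to the scale and rounded
#'   to integers (a realistic Likert fixture); if `FALSE` (default) they are
#'   left continuous, matching a pure latent-plus-noise model.
#' @param latent_unit `"sentence_type"` (default) assigns one latent pair
#'   per sentence-type condition; `"item"` draws an independent pair per
#'   item.
#' @param seed Integer seed; every generator call with the same config and
#'   seed is byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_units = 15, rho = 0.9, latent_low = 0,
                       latent_high = 5, noise_sd = 1, n_per_cell = 13,
                       n_participants = 39, items_per_block = 30,
                       n_items_per_type = 6, discretize = FALSE,
                       latent_unit = c("sentence_type", "item"),
                       seed = NULL) {
  latent_unit <- match.arg(latent_unit)
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    abort("rho must lie in (0, 1]", class = "statrace_domain_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "statrace_domain_error")
  }
  if (latent_low >= latent_high) {
    abort("latent_low must be below latent_high",
          class = "statrace_domain_error")
  }
  if (n_units * n_items_per_type < 2 * items_per_block) {
    abort(paste0("item pool (", n_units * n_items_per_type,
                 ") smaller than two blocks (", 2 * items_per_block, ")"),
          class = "statrace_config_error")
  }
  structure(list(
    n_units = as.integer(n_units), rho = rho, latent_low = latent_low,
    latent_high = latent_high, noise_sd = noise_sd,
    n_per_cell = as.integer(n_per_cell),
    n_participants = as.integer(n_participants),
    items_per_block = as.integer(items_per_block),
    n_items_per_type = as.integer(n_items_per_type),
    discretize = isTRUE(discretize), latent_unit = latent_unit,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

# sample() without the length-1 surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Draw correlated latent consensus means
#'
#' Each unit carries two latent properties: the true consensus mean under
#' acceptability instructions (`u1`) and under grammaticality instructions
#' (`u2`). `u1` is uniform on the rating scale; `u2 = u1 + e` with Gaussian
#' `e` whose variance is solved analytically so the population correlation
#' of the pair equals `rho`:
#' `sd(e) = sqrt(Var(u1) * (1 / rho^2 - 1))`, `Var(u1) = (high - low)^2 / 12`.
#' At `rho = 1` the two latents coincide: a one-factor world. `u2` is not
#' clipped to the scale, preserving the additive noise model.
#'
#' @param n_units Number of units.
#' @param rho Target correlation in (0, 1].
#' @param seed Optional integer seed.
#' @param latent_low,latent_high Scale bounds (defaults 0 and 5).
#' @return Tibble with columns `unit_id`, `u1`, `u2`.
#' @examples
#' lat <- sample_latents(1000, rho = 0.9, seed = 1)
#' cor(lat$u1, lat$u2)
#' @export
sample_latents <- function(n_units, rho, seed = NULL, latent_low = 0,
                           latent_high = 5) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    abort("rho must lie in (0, 1]", class = "statrace_domain_error")
  }
  local_seed_if(seed)
  u1 <- runif(n_units, latent_low, latent_high)
  sigma <- sqrt((latent_high - latent_low)^2 / 12 * (1 / rho^2 - 1))
  u2 <- if (sigma > 0) u1 + rnorm(n_units, 0, sigma) else u1
  tibble::tibble(
    unit_id = sprintf("type%02d", seq_len(n_units)),
    u1 = u1, u2 = u2
  )
}

#' Generate ratings around latent consensus means
#'
#' For every unit and both instruction conditions, draws `n_per_cell`
#' ratings equal to the unit's latent mean for that condition plus
#' Gaussian noise. This is the minimal cell-structured simulation used for
#' power and calibration studies; [generate_experiment()] layers the full
#' participant/block design on top of the same model.
#'
#' @param latents Tibble from [sample_latents()] (`unit_id`, `u1`, `u2`).
#' @param n_per_cell Ratings per unit per condition.
#' @param noise_sd Observation noise standard deviation.
#' @param discretize If `TRUE`, clip to `[0, 5]` and round to integers.
#' @param seed Optional integer seed.
#' @return A ratings tibble in the standard schema. Pseudo-participant ids
#'   differ across conditions so no (participant, item) pair repeats.
#' @export
sample_ratings <- function(latents, n_per_cell = 13, noise_sd = 1,
                           discretize = FALSE, seed = NULL) {
  if (nrow(latents) == 0) {
    abort("latents must be nonempty", class = "statrace_domain_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "statrace_domain_error")
  }
  local_seed_if(seed)
  n_units <- nrow(latents)
  per_cond <- function(cond, mu, tag) {
    tibble::tibble(
      participant_id = rep(sprintf("sim%s%04d", tag, seq_len(n_per_cell)),
                           times = n_units),
      item_id = rep(latents$unit_id, each = n_per_cell),
      sentence_type = rep(latents$unit_id, each = n_per_cell),
      variant = "base",
      condition = cond,
      rating = rep(mu, each = n_per_cell) +
        rnorm(n_units * n_per_cell, 0, noise_sd),
      rt_ms = 7700,
      block_index = if (cond == "acceptability") 0L else 1L,
      is_attention_check = FALSE
    )
  }
  out <- dplyr::bind_rows(
    per_cond("acceptability", latents$u1, "A"),
    per_cond("grammaticality", latents$u2, "G")
  )
  if (discretize) {
    out$rating <- round(pmin(5, pmax(0, out$rating)))
  }
  out
}

#' Simulate a full rating experiment
#'
#' Generates a complete synthetic study: an item pool stratified over
#' sentence types, participants who each rate two blocks (one per
#' instruction condition) of `items_per_block` probes drawn without
#' replacement -- so nobody sees a sentence twice -- with draws uniform over
#' sentence type, and two fixed attention-check items appended to the
#' grammaticality block. Ratings follow the latent-plus-noise model of
#' [sample_latents()] and [sample_ratings()]. Attention checks are answered
#' correctly; use [plant_exclusions()] to create violations.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `ratings` and `participants` in the standard
#'   schemas, plus the drawn `latents`.
#' @export
generate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed_if(config$seed)
  types <- sprintf("type%02d", seq_len(config$n_units))
  pool <- tibble::tibble(
    sentence_type = rep(types, each = config$n_items_per_type),
    item_id = paste0(rep(types, each = config$n_items_per_type), "_i",
                     sprintf("%02d", seq_len(config$n_items_per_type)))
  )
  latents <- sample_latents(config$n_units, config$rho,
                            latent_low = config$latent_low,
                            latent_high = config$latent_high)
  if (config$latent_unit == "item") {
    item_lat <- sample_latents(nrow(pool), config$rho,
                               latent_low = config$latent_low,
                               latent_high = config$latent_high)
    pool$u1 <- item_lat$u1
    pool$u2 <- item_lat$u2
  } else {
    pool$u1 <- latents$u1[match(pool$sentence_type, latents$unit_id)]
    pool$u2 <- latents$u2[match(pool$sentence_type, latents$unit_id)]
  }

  if (config$n_participants == 0) {
    return(list(
      ratings = read_write_template_ratings(),
      participants = read_write_template_participants(),
      latents = latents
    ))
  }

  draw_participant <- function(pid) {
    # one pass of stratified sampling: 2 * items_per_block items, each draw
    # picking a sentence type uniformly among types with items left
    n_draw <- 2L * config$items_per_block
    remaining <- split(pool$item_id, pool$sentence_type)
    drawn <- character(n_draw)
    for (d in seq_len(n_draw)) {
      open <- names(remaining)[lengths(remaining) > 0]
      ty <- resample(open, 1)
      it <- resample(remaining[[ty]], 1)
      remaining[[ty]] <- setdiff(remaining[[ty]], it)
      drawn[d] <- it
    }
    cond_order <- resample(rating_conditions, 2)
    blocks <- list(drawn[seq_len(config$items_per_block)],
                   drawn[-seq_len(config$items_per_block)])
    rows <- purrr::map2(blocks, seq_along(blocks), function(items, b) {
      cond <- cond_order[b]
      idx <- match(items, pool$item_id)
      mu <- if (cond == "acceptability") pool$u1[idx] else pool$u2[idx]
      tibble::tibble(
        participant_id = pid,
        item_id = items,
        sentence_type = pool$sentence_type[idx],
        variant = "base",
        condition = cond,
        rating = mu + rnorm(length(items), 0, config$noise_sd),
        rt_ms = 7700,
        block_index = b - 1L,
        is_attention_check = FALSE
      )
    })
    g_block <- which(cond_order == "grammaticality")
    attn <- tibble::tibble(
      participant_id = pid,
      item_id = c("attn_high", "attn_low"),
      sentence_type = "attention_check",
      variant = c("high", "low"),
      condition = "grammaticality",
      rating = c(5, 0),
      rt_ms = 7700,
      block_index = g_block - 1L,
      is_attention_check = TRUE
    )
    dplyr::bind_rows(rows[[1]], rows[[2]], attn)
  }

  pids <- sprintf("p%03d", seq_len(config$n_participants))
  ratings <- purrr::map(pids, draw_participant) |> dplyr::bind_rows()
  if (config$discretize) {
    ratings$rating <- round(pmin(5, pmax(0, ratings$rating)))
  }
  participants <- tibble::tibble(
    participant_id = pids,
    age = resample(18:71, config$n_participants, replace = TRUE),
    gender = resample(c("female", "male", "declined"),
                      config$n_participants, replace = TRUE),
    native_english = TRUE,
    completed = TRUE,
    total_time_s = 600
  )
  list(ratings = ratings, participants = participants, latents = latents)
}

read_write_template_ratings <- function() {
  tibble::tibble(
    participant_id = character(), item_id = character(),
    sentence_type = character(), variant = character(),
    condition = character(), rating = double(), rt_ms = double(),
    block_index = integer(), is_attention_check = logical()
  )
}

read_write_template_participants <- function() {
  tibble::tibble(
    participant_id = character(), age = double(), gender = character(),
    native_english = logical(), completed = logical(), total_time_s = double()
  )
}

#' Plant exclusion-triggering participants into a simulated experiment
#'
#' Modifies designated participants so that exactly the requested exclusion
#' criteria fire downstream in [apply_exclusions()]: `"non_native"` flips
#' the native-speaker flag, `"incomplete"` clears the completion flag,
#' `"fast"` sets total participation time to 180 s (under the 4-minute
#' threshold), and `"attention_fail"` raises the rating of the
#' known-ungrammatical check item above the lowest two response options.
#' Listing a participant under several criteria makes them a
#' multiple-criteria exclusion.
#'
#' @param tables List with `ratings` and `participants`
#'   (as from [generate_experiment()]).
#' @param spec Tibble/data frame with columns `participant_id` and
#'   `criterion` (one row per planted violation).
#' @return The modified list of tables.
#' @export
plant_exclusions <- function(tables, spec) {
  spec <- tibble::as_tibble(spec)
  if (nrow(spec) == 0) return(tables)
  ratings <- tables$ratings
  participants <- tables$participants
  unknown <- setdiff(spec$participant_id, participants$participant_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown participant(s): ", paste(unknown, collapse = ", ")),
          class = "statrace_domain_error")
  }
  bad <- setdiff(spec$criterion,
                 c("non_native", "incomplete", "fast", "attention_fail"))
  if (length(bad) > 0) {
    abort(paste0("unknown criterion: ", paste(bad, collapse = ", ")),
          class = "statrace_domain_error")
  }
  for (k in seq_len(nrow(spec))) {
    pid <- spec$participant_id[k]
    i <- match(pid, participants$participant_id)
    switch(spec$criterion[k],
      non_native = { participants$native_english[i] <- FALSE },
      incomplete = { participants$completed[i] <- FALSE },
      fast = { participants$total_time_s[i] <- 180 },
      attention_fail = {
        row <- which(ratings$participant_id == pid &
                       ratings$is_attention_check &
                       ratings$variant == "low")
        if (length(row) == 0) {
          abort(paste0("participant ", pid, " has no attention-check record"),
                class = "statrace_domain_error")
        }
        ratings$rating[row] <- 3
      })
  }
  list(ratings = ratings, participants = participants,
       latents = tables$latents)
}
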