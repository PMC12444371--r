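#' Generate a synthetic dish attribute table
#'
#' Draws one site's dishes with vegetarian flags and per-serving carbon
#' footprint / saturated-fat attributes. Log carbon footprint and log SFA are
#' sampled from a bivariate normal with correlation
#' `config$attribute_correlation` and exponentiated, so both attributes are
#' strictly positive and their association is controlled on the log scale.
#' Dishes `1..n_vegetarian` are flagged vegetarian; vegetarian dishes receive
#' no systematic attribute offset (the generator models no class difference
#' in footprint by default).
#'
#' @param config A [site_config()].
#' @return A tibble with columns `dish_id` (integer), `name`, `vegetarian`
#'   (logical), `cf_g_co2e` (g CO2e per serving), `sfa_g` (g per serving).
#' @examples
#' dishes <- generate_dishes(site_config(seed = 7))
#' table(dishes$vegetarian)
#' @export
generate_dishes <- function(config) {
  validate_site_config(config)
  n <- config$n_dishes
  rho <- config$attribute_correlation
  draws <- with_stage_seed(config$seed, "dishes", {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    list(z1 = z1, z2 = z2)
  })
  log_cf <- config$cf_log_mean + config$cf_log_sd * draws$z1
  # Cholesky factor of a 2x2 correlation matrix
  log_sfa <- config$sfa_log_mean +
    config$sfa_log_sd * (rho * draws$z1 + sqrt(1 - rho^2) * draws$z2)
  veg <- seq_len(n) <= config$n_vegetarian
  tibble::tibble(
    dish_id = seq_len(n),
    name = sprintf("%s dish %02d", ifelse(veg, "Vegetarian", "Meat"),
                   seq_len(n)),
    vegetarian = veg,
    cf_g_co2e = exp(log_cf),
    sfa_g = exp(log_sfa)
  )
}

#' Generate latent dish utilities for a synthetic cohort
#'
#' For each participant `p` and dish `i`, utility
#' `u[p, i] = m[i] + e[p, i]`: `m` is the site's population-mean utility
#' vector (SD `utility_population_spread`, drawn once) and `e[p, i]` the
#' participant deviation (SD `utility_heterogeneity`). The utilities are the
#' latent quantity behind the simulated 2AFC responses; real studies observe
#' only the choices.
#'
#' @param config A [site_config()].
#' @param dishes Dish table from [generate_dishes()] (supplies the dish ids).
#' @return A numeric matrix, participants in rows (named `P001`, ...), dishes
#'   in columns (named by `dish_id`).
#' @export
generate_latent_utilities <- function(config, dishes) {
  validate_site_config(config)
  stopifnot(nrow(dishes) == config$n_dishes)
  n_p <- config$n_participants
  n_d <- config$n_dishes
  u <- with_stage_seed(config$seed, "utilities", {
    m <- stats::rnorm(n_d, sd = config$utility_population_spread)
    e <- matrix(stats::rnorm(n_p * n_d, sd = config$utility_heterogeneity),
                nrow = n_p, ncol = n_d)
    sweep(e, 2L, m, `+`)
  })
  rownames(u) <- sprintf("P%03d", seq_len(n_p))
  colnames(u) <- dishes$dish_id
  u
}

#' Simulate a complete round-robin 2AFC choice task
#'
#' Presents every unordered pair of dishes once to every participant
#' (`choose(n_dishes, 2)` trials each; 105 for 15 dishes) in a randomized
#' per-participant order. Dish `a` is chosen over `b` with probability
#' `plogis((u[a] - u[b]) / choice_temperature)`; at temperature 0 the
#' higher-utility dish always wins, with exact utility ties broken toward the
#' lower dish id so the degenerate path stays deterministic.
#'
#' @param utilities Utility matrix from [generate_latent_utilities()].
#' @param config The same [site_config()] used to generate the utilities.
#' @return A tibble of trials: `participant_id`, `dish_a`, `dish_b`
#'   (with `dish_a < dish_b`), `chosen`.
#' @examples
#' cfg <- site_config(seed = 3)
#' trials <- simulate_2afc(generate_latent_utilities(cfg, generate_dishes(cfg)), cfg)
#' nrow(trials) / cfg$n_participants  # 105 trials per participant
#' @export
simulate_2afc <- function(utilities, config) {
  validate_site_config(config)
  if (config$choice_temperature < 0) {
    stop("invalid site_config: choice_temperature must be nonnegative",
         call. = FALSE)
  }
  n_d <- ncol(utilities)
  n_p <- nrow(utilities)
  stopifnot(n_d == config$n_dishes, n_p == config$n_participants)
  dish_ids <- as.integer(colnames(utilities))
  pairs <- utils::combn(n_d, 2L)  # columns: (a, b) with a < b
  n_trials <- ncol(pairs)
  temp <- config$choice_temperature

  with_stage_seed(config$seed, "trials", {
    res <- vector("list", n_p)
    for (p in seq_len(n_p)) {
      ord <- sample.int(n_trials)
      a <- pairs[1L, ord]
      b <- pairs[2L, ord]
      du <- unname(utilities[p, a] - utilities[p, b])
      if (temp == 0) {
        # deterministic responder; ties (du == 0) go to the lower dish id
        pick_a <- du >= 0
      } else {
        pick_a <- stats::runif(n_trials) < stats::plogis(du / temp)
      }
      res[[p]] <- tibble::tibble(
        participant_id = rownames(utilities)[p],
        dish_a = dish_ids[a],
        dish_b = dish_ids[b],
        chosen = ifelse(pick_a, dish_ids[a], dish_ids[b])
      )
    }
    dplyr::bind_rows(res)
  })
}

#' Generate a full synthetic site in one call
#'
#' Convenience wrapper chaining [generate_dishes()],
#' [generate_latent_utilities()] and [simulate_2afc()].
#'
#' @param config A [site_config()].
#' @return A list with elements `config`, `dishes`, `utilities`, `trials`.
#' @export
generate_site <- function(config) {
  dishes <- generate_dishes(config)
  utilities <- generate_latent_utilities(config, dishes)
  trials <- simulate_2afc(utilities, config)
  list(config = config, dishes = dishes, utilities = utilities,
       trials = trials)
}
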