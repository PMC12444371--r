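#' Configuration for one synthetic hospital site
#'
#' Bundles every parameter of the synthetic-cohort generator: the menu
#' structure (number of dishes and how many are vegetarian), the cohort size,
#' the latent preference model, and the dish-attribute model. The defaults
#' reproduce the standardized study design: 15 dishes per site (5 vegetarian +
#' 10 meat, i.e. 3 options per day over 5 weekdays) assessed by 50
#' participants, each completing a complete round-robin of pairwise choices.
#'
#' @details
#' Preferences are generated from a latent-utility model: dish `i` has a
#' population-mean utility `m[i] ~ N(0, utility_population_spread^2)` drawn
#' once per site, and participant `p` perceives `u[p, i] = m[i] + e[p, i]`
#' with `e[p, i] ~ N(0, utility_heterogeneity^2)`. Pairwise choices follow a
#' Bradley--Terry/logistic rule on utility differences with noise scale
#' `choice_temperature`; at temperature 0 the responder is perfectly
#' transitive (always picks the higher-utility dish).
#'
#' Carbon footprint (g CO2e per serving) and saturated-fat content (g per
#' serving) are drawn from a correlated bivariate normal on the log scale and
#' exponentiated, so both are strictly positive. `attribute_correlation` is
#' the latent (log-scale) correlation between the two attributes. Default
#' location/scale give per-serving carbon footprints of roughly 1--6 kg CO2e
#' and SFA contents of roughly 5--30 g, in line with hot main dishes.
#'
#' @param n_dishes Number of dishes on the site's weekly menu.
#' @param n_vegetarian How many of the dishes are vegetarian
#'   (`0 < n_vegetarian < n_dishes`).
#' @param n_participants Cohort size for the 2AFC task.
#' @param utility_population_spread SD of the population-mean dish utilities
#'   (between-dish spread shared by the whole cohort).
#' @param utility_heterogeneity SD of the participant-level utility
#'   deviations; 0 makes all participants identical.
#' @param choice_temperature Noise scale of the logistic choice rule; 0 gives
#'   a deterministic (transitive) responder.
#' @param cf_log_mean,cf_log_sd Mean and SD of log carbon footprint
#'   (log g CO2e per serving).
#' @param sfa_log_mean,sfa_log_sd Mean and SD of log SFA content
#'   (log g per serving).
#' @param attribute_correlation Latent log-scale correlation between carbon
#'   footprint and SFA, in `[-1, 1]`.
#' @param seed Integer seed; every random draw for the site flows from it.
#'
#' @return An object of class `site_config` (a named list).
#' @examples
#' cfg <- site_config(seed = 1)
#' cfg$n_dishes
#' @export
site_config <- function(n_dishes = 15L,
                        n_vegetarian = 5L,
                        n_participants = 50L,
                        utility_population_spread = 1,
                        utility_heterogeneity = 1,
                        choice_temperature = 1,
                        cf_log_mean = log(2200),
                        cf_log_sd = 0.45,
                        sfa_log_mean = log(12),
                        sfa_log_sd = 0.5,
                        attribute_correlation = 0.2,
                        seed = 1L) {
  cfg <- list(
    n_dishes = as.integer(n_dishes),
    n_vegetarian = as.integer(n_vegetarian),
    n_participants = as.integer(n_participants),
    utility_population_spread = utility_population_spread,
    utility_heterogeneity = utility_heterogeneity,
    choice_temperature = choice_temperature,
    cf_log_mean = cf_log_mean,
    cf_log_sd = cf_log_sd,
    sfa_log_mean = sfa_log_mean,
    sfa_log_sd = sfa_log_sd,
    attribute_correlation = attribute_correlation,
    seed = as.integer(seed)
  )
  class(cfg) <- "site_config"
  validate_site_config(cfg)
  cfg
}

validate_site_config <- function(cfg) {
  stopifnot(inherits(cfg, "site_config"))
  if (is.na(cfg$n_dishes) || cfg$n_dishes < 2L) {
    stop("invalid site_config: n_dishes must be an integer >= 2", call. = FALSE)
  }
  if (is.na(cfg$n_vegetarian) || cfg$n_vegetarian <= 0L ||
      cfg$n_vegetarian >= cfg$n_dishes) {
    stop("invalid site_config: n_vegetarian must satisfy 0 < n_vegetarian < n_dishes",
         call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 1L) {
    stop("invalid site_config: n_participants must be >= 1", call. = FALSE)
  }
  for (f in c("utility_population_spread", "utility_heterogeneity",
              "choice_temperature", "cf_log_sd", "sfa_log_sd")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("invalid site_config: %s must be a nonnegative real", f),
           call. = FALSE)
    }
  }
  if (!is.finite(cfg$attribute_correlation) ||
      abs(cfg$attribute_correlation) > 1) {
    stop("invalid site_config: attribute_correlation must lie in [-1, 1]",
         call. = FALSE)
  }
  if (is.na(cfg$seed)) {
    stop("invalid site_config: seed must be a finite integer", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf(
    "<site_config> %d dishes (%d vegetarian), %d participants, seed %d\n",
    x$n_dishes, x$n_vegetarian, x$n_participants, x$seed))
  cat(sprintf(
    "  utilities: spread %.3g, heterogeneity %.3g, temperature %.3g\n",
    x$utility_population_spread, x$utility_heterogeneity,
    x$choice_temperature))
  cat(sprintf(
    "  attributes: CF lognormal(%.3g, %.3g), SFA lognormal(%.3g, %.3g), cor %.3g\n",
    x$cf_log_mean, x$cf_log_sd, x$sfa_log_mean, x$sfa_log_sd,
    x$attribute_correlation))
  invisible(x)
}

# Evaluate `expr` under a deterministic RNG stream derived from (seed, stage),
# restoring the caller's RNG state afterwards. Stage offsets keep the dish,
# utility and trial draws independent while flowing from one config seed.
with_stage_seed <- function(seed, stage, expr) {
  stage_offsets <- c(dishes = 101L, utilities = 211L, trials = 307L,
                     baseline = 401L)
  off <- stage_offsets[[stage]]
  derived <- (as.integer(seed) %% 1000000L) * 1000L + off
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derived)
  expr
}
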