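#' Optimization objective
#'
#' Three objectives are supported: minimize mean weekly carbon footprint
#' (`"cf"`), minimize mean weekly SFA intake (`"sfa"`), or minimize both
#' jointly (`"joint"`). The joint objective is the equal-weight scalarization
#' of the two baseline-normalized percent changes,
#' `w_cf * pct_change_cf + w_sfa * pct_change_sfa` with `w = (0.5, 0.5)`:
#' percent changes are dimensionless, so equal weights are meaningful across
#' the incommensurate units (g CO2e vs g SFA), which a raw-gram weighting
#' would not be. Weights are configurable but must be nonnegative and sum
#' to 1; single-variable targets ignore them.
#'
#' @param target One of `"cf"`, `"sfa"`, `"joint"`.
#' @param weights For `"joint"`: `c(w_cf, w_sfa)`, nonnegative, summing to 1.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(target = c("cf", "sfa", "joint"),
                           weights = c(0.5, 0.5)) {
  target <- match.arg(target)
  stopifnot(length(weights) == 2L, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12)
  structure(list(target = target, weights = weights),
            class = "objective_spec")
}

#' Evaluate every feasible menu against a baseline
#'
#' Enumerates the feasible menu space (or takes a pre-enumerated matrix),
#' predicts cohort outcomes for every menu, and expresses each as a percent
#' change versus the baseline menu:
#' `pct_change = 100 * (mean - baseline_mean) / baseline_mean`. A negative
#' value is a reduction. The baseline is itself a feasible menu, so it
#' appears in the stream with both percent changes exactly 0. The joint
#' score is the weighted mean of the two percent changes.
#'
#' The evaluation is vectorized over menus (one `max.col` pass per
#' participant per day), so the full 113,400- or 340,200-menu space of a
#' 15-dish site evaluates in seconds.
#'
#' @param dishes Dish table.
#' @param profiles Cohort preference profiles (see [rank_participants()]).
#' @param constraint A [menu_constraint()]; the baseline must satisfy it.
#' @param baseline A [weekly_menu()]; the reference for percent changes.
#' @param menus Optional pre-enumerated menu matrix from
#'   [enumerate_menus()]; enumerated from `dishes` + `constraint` if `NULL`.
#' @param weights Joint-score weights, as in [objective_spec()].
#' @return A tibble with one row per menu: `menu_index`, `mean_weekly_cf`,
#'   `mean_weekly_sfa`, `pct_change_cf`, `pct_change_sfa`, `joint_score`.
#'   The menu matrix is attached as attribute `"menus"` (row `i` = menu
#'   `menu_index i`) and the baseline's row index as `"baseline_index"`.
#' @export
evaluate_menus <- function(dishes, profiles, constraint = menu_constraint(),
                           baseline, menus = NULL, weights = c(0.5, 0.5)) {
  baseline <- canonicalize_menu(baseline)
  check_menu(baseline, dishes, constraint)
  if (is.null(menus)) menus <- enumerate_menus(dishes, constraint)
  n <- nrow(menus)
  if (n == 0L) stop("empty menu stream", call. = FALSE)
  n_days <- ncol(menus) %/% 3L

  rk <- profiles_rank_matrix(profiles)
  dids <- as.integer(colnames(rk))
  cf <- dishes$cf_g_co2e[match(dids, dishes$dish_id)]
  sfa <- dishes$sfa_g[match(dids, dishes$dish_id)]
  pos <- match(menus, dids); dim(pos) <- dim(menus)

  cf_tot <- numeric(n); sfa_tot <- numeric(n)
  idx <- seq_len(n)
  for (d in seq_len(n_days)) {
    day_pos <- pos[, (3L * d - 2L):(3L * d), drop = FALSE]
    for (p in seq_len(nrow(rk))) {
      r <- rk[p, ]
      day_ranks <- r[day_pos]; dim(day_ranks) <- dim(day_pos)
      chosen <- day_pos[cbind(idx, max.col(-day_ranks, ties.method = "first"))]
      cf_tot <- cf_tot + cf[chosen]
      sfa_tot <- sfa_tot + sfa[chosen]
    }
  }
  mean_cf <- cf_tot / nrow(rk)
  mean_sfa <- sfa_tot / nrow(rk)

  base_out <- cohort_outcomes(profiles, baseline, dishes)
  pct_cf <- 100 * (mean_cf - base_out$mean_weekly_cf) / base_out$mean_weekly_cf
  pct_sfa <- 100 * (mean_sfa - base_out$mean_weekly_sfa) / base_out$mean_weekly_sfa

  ev <- tibble::tibble(
    menu_index = idx,
    mean_weekly_cf = mean_cf,
    mean_weekly_sfa = mean_sfa,
    pct_change_cf = pct_cf,
    pct_change_sfa = pct_sfa,
    joint_score = weights[1L] * pct_cf + weights[2L] * pct_sfa
  )
  base_flat <- as.vector(t(unclass(baseline)))
  base_idx <- which(colSums(t(menus) != base_flat) == 0L)
  if (length(base_idx) != 1L) {
    stop("baseline menu not found (exactly once) in the enumerated stream",
         call. = FALSE)
  }
  # the baseline row's percent changes are identically 0 by construction
  ev$pct_change_cf[base_idx] <- 0
  ev$pct_change_sfa[base_idx] <- 0
  ev$joint_score[base_idx] <- 0
  attr(ev, "menus") <- menus
  attr(ev, "baseline_index") <- base_idx
  ev
}

#' Select the optimal menu(s) under an objective
#'
#' Returns every menu attaining the minimum of the objective
#' (`mean_weekly_cf`, `mean_weekly_sfa`, or `joint_score`) and designates
#' the first in canonical enumeration order as the representative.
#'
#' @param evaluations Output of [evaluate_menus()].
#' @param objective An [objective_spec()].
#' @param tol Relative tolerance for collecting co-optimal menus. Menus
#'   whose predicted selections coincide are mathematically tied but their
#'   attribute sums accumulate in different orders, so exact floating-point
#'   equality would split genuine ties arbitrarily.
#' @return A list: `optima` (tibble of all co-optimal rows), `representative`
#'   (one-row tibble), `menu` (the representative as a [weekly_menu()], when
#'   the menu matrix is attached), `objective`.
#' @export
select_optimal <- function(evaluations, objective = objective_spec("joint"),
                           tol = 1e-9) {
  stopifnot(inherits(objective, "objective_spec"))
  if (nrow(evaluations) == 0L) stop("empty evaluation stream", call. = FALSE)
  obj <- switch(objective$target,
                cf = evaluations$mean_weekly_cf,
                sfa = evaluations$mean_weekly_sfa,
                joint = objective$weights[1L] * evaluations$pct_change_cf +
                        objective$weights[2L] * evaluations$pct_change_sfa)
  m <- min(obj)
  hit <- which(obj - m <= tol * max(1, abs(m)))
  optima <- evaluations[hit, , drop = FALSE]
  menus <- attr(evaluations, "menus")
  rep_row <- optima[which.min(optima$menu_index), , drop = FALSE]
  list(
    optima = optima,
    representative = rep_row,
    menu = if (!is.null(menus)) menu_from_row(menus[rep_row$menu_index, ]),
    objective = objective
  )
}

#' Summarize one site's optimization results
#'
#' Runs the full evaluation once and reports the site-level summary: the
#' baseline cohort means and the percent reductions achieved when targeting
#' carbon footprint alone, SFA alone, and both variables under the
#' equal-weight joint objective (for the joint optimum, both variables'
#' percent changes are reported).
#'
#' @inheritParams evaluate_menus
#' @param evaluations Optional precomputed [evaluate_menus()] result.
#' @return A one-row tibble: `baseline_weekly_cf`, `baseline_weekly_sfa`,
#'   `pct_cf_single`, `pct_sfa_single`, `pct_cf_joint`, `pct_sfa_joint`,
#'   `n_menus`, `n_joint_optima`.
#' @export
summarize_site <- function(dishes, profiles, constraint = menu_constraint(),
                           baseline, evaluations = NULL,
                           weights = c(0.5, 0.5)) {
  if (is.null(evaluations)) {
    evaluations <- evaluate_menus(dishes, profiles, constraint, baseline,
                                  weights = weights)
  }
  base_idx <- attr(evaluations, "baseline_index")
  opt_cf <- select_optimal(evaluations, objective_spec("cf"))
  opt_sfa <- select_optimal(evaluations, objective_spec("sfa"))
  opt_joint <- select_optimal(evaluations, objective_spec("joint", weights))
  tibble::tibble(
    baseline_weekly_cf = evaluations$mean_weekly_cf[base_idx],
    baseline_weekly_sfa = evaluations$mean_weekly_sfa[base_idx],
    pct_cf_single = opt_cf$representative$pct_change_cf,
    pct_sfa_single = opt_sfa$representative$pct_change_sfa,
    pct_cf_joint = opt_joint$representative$pct_change_cf,
    pct_sfa_joint = opt_joint$representative$pct_change_sfa,
    n_menus = nrow(evaluations),
    n_joint_optima = nrow(opt_joint$optima)
  )
}
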