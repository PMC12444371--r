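#' Predict one participant's choice for a single day
#'
#' The choice model: each participant selects, among the three dishes
#' offered that day, the one they rank most highly (smallest rank number).
#' Selection is purely rank-driven and deterministic; any stochasticity in
#' the system lives in the synthetic response generator, not here.
#'
#' @param profile One participant's preference profile: a tibble with
#'   columns `dish_id` and `rank` covering every dish.
#' @param offered The day's offered dishes (3 dish ids).
#' @return The chosen dish id.
#' @export
predict_day <- function(profile, offered) {
  offered <- as.integer(offered)
  stopifnot(length(offered) == 3L)
  pos <- match(offered, profile$dish_id)
  if (anyNA(pos)) {
    stop(sprintf("offered dish(es) absent from the ranking: %s",
                 paste(offered[is.na(pos)], collapse = ", ")), call. = FALSE)
  }
  offered[which.min(profile$rank[pos])]
}

#' Predict one participant's selections across a weekly menu
#'
#' Applies [predict_day()] independently to each day. Because the menu is a
#' partition (no dish appears twice in a week), the five selections are
#' distinct.
#'
#' @inheritParams predict_day
#' @param menu A [weekly_menu()].
#' @return Integer vector of chosen dish ids, one per day.
#' @export
predict_week <- function(profile, menu) {
  vapply(seq_len(nrow(menu)), function(d) predict_day(profile, menu[d, ]),
         integer(1L))
}

#' Cohort-level weekly outcomes under one menu
#'
#' Predicts every participant's five selections under the menu and averages
#' the per-participant weekly totals: mean weekly carbon footprint
#' (g CO2e per person per week) and mean weekly SFA intake (g per person per
#' week). Averaging across participants is how heterogeneity in preference
#' enters the cohort outcome.
#'
#' @param profiles Preference profiles for the whole cohort
#'   (`participant_id`, `dish_id`, `rank`), e.g. from [rank_participants()].
#' @param menu A [weekly_menu()].
#' @param dishes Dish table with `cf_g_co2e` and `sfa_g`.
#' @return A list: `mean_weekly_cf`, `mean_weekly_sfa`, and `selections`
#'   (matrix of chosen dish ids, participants x days).
#' @export
cohort_outcomes <- function(profiles, menu, dishes) {
  check_menu(menu, dishes)
  rk <- profiles_rank_matrix(profiles)
  if (nrow(rk) == 0L) stop("empty cohort", call. = FALSE)
  dids <- as.integer(colnames(rk))
  cf <- dishes$cf_g_co2e[match(dids, dishes$dish_id)]
  sfa <- dishes$sfa_g[match(dids, dishes$dish_id)]
  sel <- matrix(NA_integer_, nrow = nrow(rk), ncol = nrow(menu),
                dimnames = list(rownames(rk), rownames(menu)))
  for (d in seq_len(nrow(menu))) {
    cols <- match(menu[d, ], dids)
    day_ranks <- rk[, cols, drop = FALSE]
    pick <- max.col(-day_ranks, ties.method = "first")
    sel[, d] <- dids[cols[pick]]
  }
  pos <- match(sel, dids); dim(pos) <- dim(sel)
  list(
    mean_weekly_cf = mean(rowSums(matrix(cf[pos], nrow = nrow(sel)))),
    mean_weekly_sfa = mean(rowSums(matrix(sfa[pos], nrow = nrow(sel)))),
    selections = sel
  )
}
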