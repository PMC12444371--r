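# Independent brute-force oracles and small-site builders.
# These deliberately avoid the package's anchor-based enumeration and
# vectorized evaluation: partitions are generated with labelled-day recursion
# and deduplicated by canonical key, and outcomes are recomputed with plain
# loops, so agreement with the package is a genuine cross-check.

# all partitions of `ids` into unordered triples, as lists of sorted triples
bf_partitions <- function(ids, day_size = 3L) {
  rec <- function(remaining) {
    if (length(remaining) == 0L) return(list(list()))
    res <- list()
    for (day in utils::combn(remaining, day_size, simplify = FALSE)) {
      rest <- setdiff(remaining, day)
      for (tail in rec(rest)) {
        res[[length(res) + 1L]] <- c(list(sort(day)), tail)
      }
    }
    res
  }
  labelled <- rec(ids)
  keys <- vapply(labelled, bf_menu_key, character(1L))
  labelled[!duplicated(keys)]
}

bf_menu_key <- function(days) {
  days <- lapply(days, sort)
  days <- days[order(vapply(days, min, numeric(1L)))]
  paste(vapply(days, paste, character(1L), collapse = ","), collapse = "|")
}

bf_feasible <- function(partitions, dishes, min_veg) {
  Filter(function(p) {
    all(vapply(p, function(day) {
      sum(dishes$vegetarian[match(day, dishes$dish_id)]) >= min_veg
    }, logical(1L)))
  }, partitions)
}

# plain-loop cohort evaluation of one menu (list of day triples)
bf_outcomes <- function(menu_days, profiles, dishes) {
  pids <- unique(profiles$participant_id)
  cf_sum <- 0; sfa_sum <- 0
  for (p in pids) {
    prof <- profiles[profiles$participant_id == p, ]
    for (day in menu_days) {
      ranks <- prof$rank[match(day, prof$dish_id)]
      chosen <- day[which.min(ranks)]
      cf_sum <- cf_sum + dishes$cf_g_co2e[dishes$dish_id == chosen]
      sfa_sum <- sfa_sum + dishes$sfa_g[dishes$dish_id == chosen]
    }
  }
  c(cf = cf_sum / length(pids), sfa = sfa_sum / length(pids))
}

# monolithic brute-force pipeline: enumerate, evaluate, select optima
bf_site_optima <- function(dishes, profiles, min_veg, baseline_days,
                           weights = c(0.5, 0.5)) {
  parts <- bf_feasible(bf_partitions(sort(dishes$dish_id)), dishes, min_veg)
  base <- bf_outcomes(baseline_days, profiles, dishes)
  ev <- t(vapply(parts, bf_outcomes, numeric(2L), profiles = profiles,
                 dishes = dishes))
  pct_cf <- 100 * (ev[, "cf"] - base["cf"]) / base["cf"]
  pct_sfa <- 100 * (ev[, "sfa"] - base["sfa"]) / base["sfa"]
  joint <- weights[1L] * pct_cf + weights[2L] * pct_sfa
  # tolerance-based minimum: menus whose selections coincide are
  # mathematically tied but accumulate sums in different orders
  near_min <- function(x) which(x - min(x) <= 1e-9 * max(1, abs(min(x))))
  i_cf <- near_min(ev[, "cf"])
  i_sfa <- near_min(ev[, "sfa"])
  i_joint <- near_min(joint)
  list(
    n_menus = length(parts),
    baseline = base,
    pct_cf_single = min(pct_cf[i_cf]),
    pct_sfa_single = min(pct_sfa[i_sfa]),
    pct_cf_joint = pct_cf[i_joint[1L]],
    pct_sfa_joint = pct_sfa[i_joint[1L]],
    cf_optima_keys = sort(vapply(parts[i_cf], bf_menu_key, character(1L))),
    sfa_optima_keys = sort(vapply(parts[i_sfa], bf_menu_key, character(1L))),
    joint_optima_keys = sort(vapply(parts[i_joint], bf_menu_key,
                                    character(1L)))
  )
}

menu_key <- function(menu) bf_menu_key(split(unclass(menu), row(menu)))

# small synthetic site (6 or 9 dishes) for oracle comparisons
toy_site <- function(n_dishes, n_veg, n_participants = 4L, seed = 1L,
                     temperature = 0.5) {
  cfg <- site_config(n_dishes = n_dishes, n_vegetarian = n_veg,
                     n_participants = n_participants, seed = seed,
                     choice_temperature = temperature)
  site <- generate_site(cfg)
  profiles <- rank_participants(site$trials, site$dishes)
  list(config = cfg, dishes = site$dishes, utilities = site$utilities,
       trials = site$trials, profiles = profiles)
}

# hand-built transitive trial table: dish i beats dish j whenever
# order[i] < order[j] (order = latent preference position)
transitive_trials <- function(dish_ids, order, participant = "P1") {
  pairs <- utils::combn(dish_ids, 2L)
  pos <- match(pairs, dish_ids); dim(pos) <- dim(pairs)
  chosen <- ifelse(order[pos[1L, ]] < order[pos[2L, ]], pairs[1L, ],
                   pairs[2L, ])
  tibble::tibble(participant_id = participant, dish_a = pairs[1L, ],
                 dish_b = pairs[2L, ], chosen = chosen)
}

# TRUE iff the rows of an enumerate_menus() matrix are strictly
# lexicographically increasing (implies no duplicates)
rows_strictly_increasing <- function(m) {
  if (nrow(m) < 2L) return(TRUE)
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1L, , drop = FALSE]
  neq <- a != b
  if (any(rowSums(neq) == 0L)) return(FALSE)
  j <- max.col(neq, ties.method = "first")
  i <- seq_len(nrow(a))
  all(a[cbind(i, j)] < b[cbind(i, j)])
}
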