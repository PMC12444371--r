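test_that("predict_day picks the best-ranked offered dish", {
  profile <- tibble::tibble(participant_id = "P1", dish_id = 1:15,
                            rank = c(3L, 7L, 12L, 1L, 2L, 4:6, 8:11, 13:15))
  # offered ranks {3, 7, 12} -> the rank-3 dish
  expect_equal(predict_day(profile, c(1L, 2L, 3L)), 1L)
  # a day offering the rank-1 dish always yields it
  expect_equal(predict_day(profile, c(4L, 2L, 3L)), 4L)
  expect_error(predict_day(profile, c(1L, 2L, 99L)), "absent")
})

test_that("daily selections across a week follow the per-day best rank", {
  # ranks over 9 dishes; menu puts the participant's best offered ranks at
  # 3, 4 and 1 across the three days
  prof <- tibble::tibble(participant_id = "P1", dish_id = 1:9, rank = 1:9)
  # canonical day order puts {1,2,7} first; best offered ranks are 1, 3, 4
  menu <- weekly_menu(list(c(3, 5, 6), c(4, 8, 9), c(1, 2, 7)))
  sel <- predict_week(prof, menu)
  expect_equal(prof$rank[match(sel, prof$dish_id)], c(1L, 3L, 4L))
  expect_equal(anyDuplicated(sel), 0L)

  # a participant whose top-5 dishes land one per day selects exactly them
  prof15 <- tibble::tibble(participant_id = "P1", dish_id = 1:15,
                           rank = 1:15)
  m <- weekly_menu(split(c(1, 6, 7, 2, 8, 9, 3, 10, 11, 4, 12, 13, 5, 14, 15),
                         rep(1:5, each = 3)))
  expect_setequal(predict_week(prof15, m), 1:5)
})

test_that("cohort outcomes equal a plain-loop recomputation", {
  site <- toy_site(15, 5, n_participants = 50L, seed = 31, temperature = 1)
  menu <- generate_baseline_menu(site$dishes, seed = 31)
  out <- cohort_outcomes(site$profiles, menu, site$dishes)
  oracle <- bf_outcomes(split(unclass(menu), row(menu)), site$profiles,
                        site$dishes)
  expect_equal(out$mean_weekly_cf, unname(oracle["cf"]))
  expect_equal(out$mean_weekly_sfa, unname(oracle["sfa"]))

  # no offered dish on any day is preferred to the selected dish
  rk <- matrix(NA_integer_, 50, 15)
  rk[cbind(match(site$profiles$participant_id,
                 unique(site$profiles$participant_id)),
           site$profiles$dish_id)] <- site$profiles$rank
  for (p in seq_len(nrow(out$selections))) {
    for (d in seq_len(ncol(out$selections))) {
      offered <- menu[d, ]
      expect_equal(min(rk[p, offered]), rk[p, out$selections[p, d]])
    }
  }
})

test_that("constant attributes and singleton cohorts behave exactly", {
  dishes <- tibble::tibble(dish_id = 1:6, name = as.character(1:6),
                           vegetarian = c(TRUE, TRUE, rep(FALSE, 4)),
                           cf_g_co2e = rep(700, 6), sfa_g = rep(3, 6))
  prof <- tibble::tibble(participant_id = "P1", dish_id = 1:6, rank = 1:6)
  menu <- weekly_menu(list(1:3, 4:6))
  out <- cohort_outcomes(prof, menu, dishes)
  expect_equal(out$mean_weekly_cf, 2 * 700)  # n_days * constant
  expect_equal(out$mean_weekly_sfa, 2 * 3)

  # singleton cohort: means equal that participant's weekly sums
  dishes$cf_g_co2e <- c(10, 20, 30, 40, 50, 60)
  out <- cohort_outcomes(prof, menu, dishes)
  expect_equal(out$mean_weekly_cf, 10 + 40)  # picks rank-best each day
})

test_that("selections depend only on ranks; outcomes scale linearly in attributes", {
  site <- toy_site(9, 3, n_participants = 6L, seed = 8)
  menu <- generate_baseline_menu(site$dishes, seed = 8)
  out1 <- cohort_outcomes(site$profiles, menu, site$dishes)
  scaled <- site$dishes
  scaled$cf_g_co2e <- scaled$cf_g_co2e * 7.5
  out2 <- cohort_outcomes(site$profiles, menu, scaled)
  expect_identical(out2$selections, out1$selections)
  expect_equal(out2$mean_weekly_cf, 7.5 * out1$mean_weekly_cf)
  expect_equal(out2$mean_weekly_sfa, out1$mean_weekly_sfa)

  # bounds: weekly mean lies within [n_days * min CF, n_days * max CF]
  expect_gte(out1$mean_weekly_cf, 3 * min(site$dishes$cf_g_co2e))
  expect_lte(out1$mean_weekly_cf, 3 * max(site$dishes$cf_g_co2e))
})

test_that("toy-site weekly selections match exhaustive hand evaluation", {
  dishes <- tibble::tibble(dish_id = 1:6, name = as.character(1:6),
                           vegetarian = c(TRUE, TRUE, rep(FALSE, 4)),
                           cf_g_co2e = c(5, 4, 9, 2, 7, 1),
                           sfa_g = c(1, 3, 2, 8, 5, 4))
  profiles <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 6),
    dish_id = rep(1:6, 2),
    rank = c(2L, 5L, 1L, 6L, 3L, 4L,   # A prefers 3 > 1 > 5 > 6 > 2 > 4
             6L, 1L, 4L, 2L, 5L, 3L))  # B prefers 2 > 4 > 6 > 3 > 5 > 1
  menu <- weekly_menu(list(c(1, 2, 4), c(3, 5, 6)))
  # A: day {1,2,4} -> 1 (rank 2); day {3,5,6} -> 3 (rank 1)
  # B: day {1,2,4} -> 2 (rank 1); day {3,5,6} -> 6 (rank 3)
  out <- cohort_outcomes(profiles, menu, dishes)
  expect_equal(out$selections["A", ], c(day1 = 1L, day2 = 3L))
  expect_equal(out$selections["B", ], c(day1 = 2L, day2 = 6L))
  expect_equal(out$mean_weekly_cf, mean(c(5 + 9, 4 + 1)))
  expect_equal(out$mean_weekly_sfa, mean(c(1 + 2, 3 + 4)))
})

test_that("menus that do not partition the dish set are rejected", {
  site <- toy_site(6, 2, n_participants = 2L, seed = 1)
  expect_error(cohort_outcomes(site$profiles,
                               weekly_menu(list(c(1, 2, 3), c(4, 5, 7))),
                               site$dishes), "partition")
  expect_error(cohort_outcomes(site$profiles[0L, ],
                               weekly_menu(list(1:3, 4:6)), site$dishes))
})
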