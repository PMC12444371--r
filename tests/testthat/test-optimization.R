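test_that("the baseline evaluates to exactly zero percent change", {
  site <- toy_site(9, 3, n_participants = 5L, seed = 2)
  baseline <- generate_baseline_menu(site$dishes, seed = 2)
  ev <- evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                       baseline)
  bi <- attr(ev, "baseline_index")
  expect_equal(ev$pct_change_cf[bi], 0)
  expect_equal(ev$pct_change_sfa[bi], 0)
  expect_equal(ev$joint_score[bi], 0)
  expect_equal(nrow(ev), count_menus(3, 6, 3, menu_constraint(1)))
  # joint score is the equal-weight mean of the two percent changes
  expect_equal(ev$joint_score,
               0.5 * ev$pct_change_cf + 0.5 * ev$pct_change_sfa)
})

test_that("an infeasible baseline is refused", {
  site <- toy_site(6, 2, n_participants = 2L, seed = 3)
  # one vegetarian dish (ids 1, 2) on each day: feasible
  ok <- evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                       weekly_menu(list(c(1, 3, 4), c(2, 5, 6))))
  expect_true(nrow(ok) > 0L)
  # both vegetarian dishes on one day leaves the other day all-meat
  expect_error(
    evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                   weekly_menu(list(c(1, 2, 4), c(3, 5, 6)))),
    "vegetarian constraint")
  # and a non-partition baseline fails before any evaluation
  expect_error(
    evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                   weekly_menu(list(c(1, 3, 4), c(2, 5, 7)))),
    "partition")
})

test_that("full pipeline matches the monolithic brute-force oracle on toy sites", {
  for (s in 1:6) {
    n <- if (s %% 2 == 0) 6L else 9L
    nv <- if (n == 6L) 2L else 3L
    site <- toy_site(n, nv, n_participants = 4L, seed = 100 + s)
    baseline <- generate_baseline_menu(site$dishes, seed = s)
    ev <- evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                         baseline)
    oracle <- bf_site_optima(site$dishes, site$profiles, 1L,
                             split(unclass(baseline), row(baseline)))
    expect_equal(nrow(ev), oracle$n_menus)
    for (tgt in c("cf", "sfa", "joint")) {
      sel <- select_optimal(ev, objective_spec(tgt))
      keys <- sort(vapply(sel$optima$menu_index, function(i) {
        menu_key(canonicalize_menu(matrix(attr(ev, "menus")[i, ], ncol = 3L,
                                          byrow = TRUE)))
      }, character(1L)))
      expect_equal(keys, oracle[[paste0(tgt, "_optima_keys")]])
    }
    summ <- summarize_site(site$dishes, site$profiles, menu_constraint(1),
                           baseline, evaluations = ev)
    expect_equal(summ$pct_cf_single, oracle$pct_cf_single)
    expect_equal(summ$pct_sfa_single, oracle$pct_sfa_single)
    expect_equal(summ$pct_cf_joint, oracle$pct_cf_joint)
    expect_equal(summ$pct_sfa_joint, oracle$pct_sfa_joint)
  }
})

test_that("a menu dominating both variables is optimal under all objectives", {
  ev <- tibble::tibble(
    menu_index = 1:4,
    mean_weekly_cf = c(50, 40, 30, 45),
    mean_weekly_sfa = c(5, 4, 3, 4.5),
    pct_change_cf = c(0, -20, -40, -10),
    pct_change_sfa = c(0, -20, -40, -10),
    joint_score = c(0, -20, -40, -10))
  for (tgt in c("cf", "sfa", "joint")) {
    sel <- select_optimal(ev, objective_spec(tgt))
    expect_equal(sel$representative$menu_index, 3L)
  }
  expect_error(select_optimal(ev[0L, ], objective_spec("cf")), "empty")
})

test_that("co-optimal menus are all reported with the canonical first as representative", {
  # identical attributes for every dish -> every menu is co-optimal
  site <- toy_site(6, 2, n_participants = 3L, seed = 5)
  dishes <- site$dishes
  dishes$cf_g_co2e <- rep(100, 6)
  dishes$sfa_g <- rep(2, 6)
  baseline <- generate_baseline_menu(dishes, seed = 5)
  ev <- evaluate_menus(dishes, site$profiles, menu_constraint(1), baseline)
  sel <- select_optimal(ev, objective_spec("joint"))
  expect_equal(nrow(sel$optima), nrow(ev))
  expect_equal(sel$representative$menu_index, 1L)
  # constant CF: reductions exactly 0 under every objective
  summ <- summarize_site(dishes, site$profiles, menu_constraint(1), baseline,
                         evaluations = ev)
  expect_equal(summ$pct_cf_single, 0)
  expect_equal(summ$pct_sfa_single, 0)
})

test_that("joint reductions never beat single-target reductions; optima never worse than baseline", {
  for (s in 1:8) {
    site <- toy_site(9, 3, n_participants = 5L, seed = 200 + s,
                     temperature = 1)
    baseline <- generate_baseline_menu(site$dishes, seed = s)
    summ <- summarize_site(site$dishes, site$profiles, menu_constraint(1),
                           baseline)
    expect_lte(summ$pct_cf_single, 0)
    expect_lte(summ$pct_sfa_single, 0)
    expect_gte(summ$pct_cf_joint, summ$pct_cf_single)
    expect_gte(summ$pct_sfa_joint, summ$pct_sfa_single)
  }
})

test_that("percent reductions and optimal menus are invariant to attribute rescaling", {
  site <- toy_site(9, 3, n_participants = 5L, seed = 17)
  baseline <- generate_baseline_menu(site$dishes, seed = 17)
  menus <- enumerate_menus(site$dishes, menu_constraint(1))
  ref <- evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                        baseline, menus = menus)
  ref_opt <- lapply(c("cf", "sfa", "joint"), function(t) {
    select_optimal(ref, objective_spec(t))$optima$menu_index
  })
  for (k in c(0.1, 3, 10)) {
    scaled <- site$dishes
    scaled$cf_g_co2e <- scaled$cf_g_co2e * k
    ev <- evaluate_menus(scaled, site$profiles, menu_constraint(1),
                         baseline, menus = menus)
    expect_equal(ev$pct_change_cf, ref$pct_change_cf)
    expect_equal(ev$pct_change_sfa, ref$pct_change_sfa)
    opt <- lapply(c("cf", "sfa", "joint"), function(t) {
      select_optimal(ev, objective_spec(t))$optima$menu_index
    })
    expect_equal(opt, ref_opt)
  }
})

test_that("tightening the constraint cannot improve the optimum", {
  site <- toy_site(9, 3, n_participants = 5L, seed = 23)
  baseline <- generate_baseline_menu(site$dishes, menu_constraint(1),
                                     seed = 23)
  for (tgt in c("cf", "sfa")) {
    opt1 <- select_optimal(
      evaluate_menus(site$dishes, site$profiles, menu_constraint(1),
                     baseline), objective_spec(tgt))
    opt0 <- select_optimal(
      evaluate_menus(site$dishes, site$profiles, menu_constraint(0),
                     baseline), objective_spec(tgt))
    col <- paste0("mean_weekly_", tgt)
    expect_gte(opt1$representative[[col]], opt0$representative[[col]])
  }
})
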