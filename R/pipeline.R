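#' Configuration for an end-to-end multi-site run
#'
#' Describes a full replica run: how many synthetic sites to generate, the
#' site-level generator settings, the menu constraint, the baseline policy,
#' and the single top-level seed from which every site's randomness is
#' derived deterministically (site `i` runs under `seed + i`).
#'
#' @param n_sites Number of sites (the standardized multi-region design uses
#'   11).
#' @param site_overrides Named list of [site_config()] arguments applied to
#'   every site (e.g. `list(n_vegetarian = 6)` for the 6-vegetarian menu
#'   variant).
#' @param constraint A [menu_constraint()].
#' @param baseline `"generate"` (sample a feasible baseline per site under
#'   the run seed) or a list of `n_sites` explicit [weekly_menu()] objects.
#' @param weights Joint-objective weights (see [objective_spec()]).
#' @param export_evaluations Also write the full per-menu evaluation table
#'   per site (the data behind a menu-space scatter plot).
#' @param seed Top-level integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_sites = 11L, site_overrides = list(),
                       constraint = menu_constraint(),
                       baseline = "generate", weights = c(0.5, 0.5),
                       export_evaluations = FALSE, seed = 1L) {
  stopifnot(n_sites >= 1L, inherits(constraint, "menu_constraint"))
  if (!identical(baseline, "generate")) {
    stopifnot(is.list(baseline), length(baseline) == n_sites)
  }
  structure(list(n_sites = as.integer(n_sites),
                 site_overrides = site_overrides,
                 constraint = constraint, baseline = baseline,
                 weights = weights,
                 export_evaluations = isTRUE(export_evaluations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline and write an artifact bundle
#'
#' For each site: generates dishes and 2AFC trials, ranks participants,
#' enumerates the feasible menu space, evaluates every menu against the
#' site's baseline, and selects the single-variable and joint optima. Each
#' site's inputs and outputs are written as plain CSV (`dishes.csv`,
#' `trials.csv`, `rankings.csv`, optionally `evaluations.csv`), so any stage
#' can be replaced file-for-file with real data. A run `manifest.json`
#' records the configuration, seed, package version, the joint-objective
#' definition, and per-site menu-space sizes and tie counts; `summary.csv`
#' holds one row per site with the baseline means and percent reductions.
#' Identical configuration + seed reproduces the bundle byte-for-byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `summary` tibble and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- vector("list", config$n_sites)
  site_meta <- vector("list", config$n_sites)

  for (i in seq_len(config$n_sites)) {
    # distinct per-site streams that do not collide across nearby run seeds
    site_seed <- config$seed * 1000L + i
    cfg <- do.call(site_config,
                   c(list(seed = site_seed), config$site_overrides))
    site_dir <- file.path(out_dir, sprintf("site_%02d", i))
    dir.create(site_dir, showWarnings = FALSE)

    site <- generate_site(cfg)
    profiles <- rank_participants(site$trials, site$dishes)
    baseline <- if (identical(config$baseline, "generate")) {
      generate_baseline_menu(site$dishes, config$constraint, seed = site_seed)
    } else {
      canonicalize_menu(config$baseline[[i]])
    }
    check_menu(baseline, site$dishes, config$constraint)

    ev <- evaluate_menus(site$dishes, profiles, config$constraint, baseline,
                         weights = config$weights)
    summ <- summarize_site(site$dishes, profiles, config$constraint,
                           baseline, evaluations = ev,
                           weights = config$weights)
    summ <- tibble::add_column(summ, site = sprintf("S%02d", i),
                               .before = 1L)
    summaries[[i]] <- summ

    readr::write_csv(site$dishes, file.path(site_dir, "dishes.csv"))
    readr::write_csv(site$trials, file.path(site_dir, "trials.csv"))
    readr::write_csv(profiles, file.path(site_dir, "rankings.csv"))
    readr::write_csv(
      tibble::tibble(day = seq_len(nrow(baseline)),
                     dishes = apply(baseline, 1L, paste, collapse = ";")),
      file.path(site_dir, "baseline_menu.csv"))
    if (config$export_evaluations) {
      readr::write_csv(ev, file.path(site_dir, "evaluations.csv"))
    }

    site_meta[[i]] <- list(
      site = sprintf("S%02d", i), seed = site_seed,
      n_dishes = cfg$n_dishes, n_vegetarian = cfg$n_vegetarian,
      n_participants = cfg$n_participants,
      n_menus_evaluated = nrow(ev),
      n_joint_optima = summ$n_joint_optima
    )
  }

  summary <- dplyr::bind_rows(summaries)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  manifest <- list(
    package = "menuswap",
    version = as.character(utils::packageVersion("menuswap")),
    seed = config$seed,
    n_sites = config$n_sites,
    min_vegetarian_per_day = config$constraint$min_vegetarian_per_day,
    joint_objective = sprintf(
      "minimize %.2f * pct_change_cf + %.2f * pct_change_sfa (baseline-normalized percent changes)",
      config$weights[1L], config$weights[2L]),
    site_overrides = config$site_overrides,
    sites = site_meta
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, manifest = manifest))
}

#' Read pipeline CSV surfaces
#'
#' Typed readers for the bundle's file formats, so real dish-attribute,
#' trial or ranking data can be dropped in place of a synthetic stage.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the documented columns.
#' @export
read_dishes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    dish_id = readr::col_integer(), name = readr::col_character(),
    vegetarian = readr::col_logical(), cf_g_co2e = readr::col_double(),
    sfa_g = readr::col_double()))
}

#' @rdname read_dishes_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    dish_a = readr::col_integer(), dish_b = readr::col_integer(),
    chosen = readr::col_integer()))
}

#' @rdname read_dishes_csv
#' @export
read_rankings_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    dish_id = readr::col_integer(), win_count = readr::col_integer(),
    rank = readr::col_integer()))
}
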