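#' Validate a 2AFC trial table against a dish table
#'
#' Checks the structural assumptions the ranking stage relies on: every
#' referenced dish id exists, the chosen dish is one of the offered pair,
#' no pair offers a dish against itself, and each participant's trials form
#' a complete round-robin (every unordered dish pair exactly once).
#' Violations are reported, never silently dropped.
#'
#' @param trials Trial tibble (`participant_id`, `dish_a`, `dish_b`,
#'   `chosen`).
#' @param dishes Dish table; `dish_id` defines the universe of valid ids.
#' @return A tibble of violations with columns `type`, `participant_id`,
#'   `dish_a`, `dish_b`, `detail`; zero rows when the table is valid.
#' @export
validate_trials <- function(trials, dishes) {
  viol <- list()
  ids <- dishes$dish_id
  add <- function(type, participant_id, dish_a, dish_b, detail) {
    tibble::tibble(type = type, participant_id = participant_id,
                   dish_a = as.integer(dish_a), dish_b = as.integer(dish_b),
                   detail = detail)
  }

  bad_id <- !(trials$dish_a %in% ids) | !(trials$dish_b %in% ids)
  if (any(bad_id)) {
    t <- trials[bad_id, ]
    viol <- c(viol, list(add("unknown_dish", t$participant_id, t$dish_a,
                             t$dish_b, "pair references a dish id not in the dish table")))
  }
  self_pair <- trials$dish_a == trials$dish_b
  if (any(self_pair)) {
    t <- trials[self_pair, ]
    viol <- c(viol, list(add("self_pair", t$participant_id, t$dish_a,
                             t$dish_b, "dish paired against itself")))
  }
  bad_choice <- trials$chosen != trials$dish_a & trials$chosen != trials$dish_b
  if (any(bad_choice)) {
    t <- trials[bad_choice, ]
    viol <- c(viol, list(add("invalid_choice", t$participant_id, t$dish_a,
                             t$dish_b, "chosen dish is neither member of the pair")))
  }

  # round-robin completeness per participant, over the dish-table universe
  all_pairs <- utils::combn(sort(ids), 2L)
  expected <- paste(all_pairs[1L, ], all_pairs[2L, ])
  seen_key <- paste(pmin(trials$dish_a, trials$dish_b),
                    pmax(trials$dish_a, trials$dish_b))
  for (p in unique(trials$participant_id)) {
    keys <- seen_key[trials$participant_id == p]
    missing <- setdiff(expected, keys)
    for (k in missing) {
      ab <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
      viol <- c(viol, list(add("missing_pair", p, ab[1L], ab[2L],
                               "unordered pair never offered to this participant")))
    }
    dup <- unique(keys[duplicated(keys)])
    for (k in dup) {
      ab <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
      viol <- c(viol, list(add("duplicate_pair", p, ab[1L], ab[2L],
                               "unordered pair offered more than once")))
    }
  }

  if (length(viol) == 0L) {
    tibble::tibble(type = character(), participant_id = character(),
                   dish_a = integer(), dish_b = integer(),
                   detail = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Rank one participant's dishes from pairwise wins
#'
#' Counts, for each dish, how many trials it won, and converts the counts
#' into a strict preference ranking (rank 1 = most preferred = most wins).
#' A perfectly transitive responder over `n` dishes produces the distinct
#' counts `n-1, n-2, ..., 0`; intransitive (cyclic) responses can tie, so a
#' deterministic tie policy is applied.
#'
#' @param trials Validated trial tibble.
#' @param participant A `participant_id` present in `trials`.
#' @param tie_rule `"head_to_head"` (default): when exactly two dishes tie on
#'   win count, the winner of their direct trial ranks first, any other tie
#'   resolves by ascending dish id; `"dish_id"`: all ties by ascending id.
#' @return A tibble (`participant_id`, `dish_id`, `win_count`, `rank`)
#'   ordered by rank; win counts are non-increasing along the ranking and
#'   sum to `choose(n_dishes, 2)`.
#' @export
rank_from_pairwise <- function(trials, participant,
                               tie_rule = c("head_to_head", "dish_id")) {
  tie_rule <- match.arg(tie_rule)
  t <- trials[trials$participant_id == participant, , drop = FALSE]
  if (nrow(t) == 0L) {
    stop(sprintf("unknown participant: %s", participant), call. = FALSE)
  }
  dish_ids <- sort(unique(c(t$dish_a, t$dish_b)))
  wins <- table(factor(t$chosen, levels = dish_ids))
  win_count <- as.integer(wins)

  ord <- order(-win_count, dish_ids)
  if (tie_rule == "head_to_head") {
    counts_sorted <- win_count[ord]
    grp <- split(seq_along(ord), match(counts_sorted, unique(counts_sorted)))
    for (g in grp) {
      if (length(g) == 2L) {
        i <- ord[g[1L]]; j <- ord[g[2L]]
        a <- dish_ids[i]; b <- dish_ids[j]
        hit <- (t$dish_a == min(a, b) & t$dish_b == max(a, b)) |
               (t$dish_a == max(a, b) & t$dish_b == min(a, b))
        won_by <- t$chosen[hit][1L]
        if (!is.na(won_by) && won_by == b) ord[g] <- c(j, i)
      }
    }
  }

  tibble::tibble(
    participant_id = participant,
    dish_id = dish_ids[ord],
    win_count = win_count[ord],
    rank = seq_along(ord)
  )
}

#' Rank every participant in a trial table
#'
#' Validates the trial table (unless `check = FALSE`) and applies
#' [rank_from_pairwise()] to each participant.
#'
#' @inheritParams rank_from_pairwise
#' @param dishes Dish table used for validation.
#' @param check Validate before ranking and abort on any violation.
#' @return A tibble of preference profiles:
#'   (`participant_id`, `dish_id`, `win_count`, `rank`).
#' @export
rank_participants <- function(trials, dishes,
                              tie_rule = c("head_to_head", "dish_id"),
                              check = TRUE) {
  tie_rule <- match.arg(tie_rule)
  if (check) {
    v <- validate_trials(trials, dishes)
    if (nrow(v) > 0L) {
      stop(sprintf("trial table failed validation: %d violation(s), first: %s (participant %s, pair %s-%s)",
                   nrow(v), v$type[1L], v$participant_id[1L], v$dish_a[1L],
                   v$dish_b[1L]), call. = FALSE)
    }
  }
  dplyr::bind_rows(lapply(unique(trials$participant_id), function(p) {
    rank_from_pairwise(trials, p, tie_rule)
  }))
}

# profiles tibble -> rank matrix (participants x dishes, dimnames set);
# rank_matrix[p, d] is participant p's rank of dish d (1 = most preferred)
profiles_rank_matrix <- function(profiles) {
  pids <- unique(profiles$participant_id)
  dids <- sort(unique(profiles$dish_id))
  m <- matrix(NA_integer_, nrow = length(pids), ncol = length(dids),
              dimnames = list(pids, dids))
  m[cbind(match(profiles$participant_id, pids),
          match(profiles$dish_id, dids))] <- profiles$rank
  if (anyNA(m)) {
    stop("profiles do not rank every dish for every participant",
         call. = FALSE)
  }
  m
}
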