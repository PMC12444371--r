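#' Minimum-vegetarian-per-day menu constraint
#'
#' @param min_vegetarian_per_day Minimum number of vegetarian dishes that
#'   must be offered on every day (0--3; default 1, the standard rule).
#' @return An object of class `menu_constraint`.
#' @export
menu_constraint <- function(min_vegetarian_per_day = 1L) {
  m <- as.integer(min_vegetarian_per_day)
  if (is.na(m) || m < 0L || m > 3L) {
    stop("min_vegetarian_per_day must be an integer in 0..3", call. = FALSE)
  }
  structure(list(min_vegetarian_per_day = m), class = "menu_constraint")
}

#' Canonicalize a weekly menu
#'
#' A weekly menu is a partition of the dish set into unordered days of three
#' dishes each; neither the order of days nor the order of dishes within a
#' day is meaningful. The canonical form sorts dish ids ascending within each
#' day and orders days by their sorted triples (equivalently, by smallest
#' member, since days are disjoint). Two menus are equal iff their canonical
#' forms are identical, and canonicalization is idempotent.
#'
#' @param days The menu's days: an `n_days x 3` matrix of dish ids, a list of
#'   `n_days` length-3 vectors, or an already-canonical `weekly_menu`.
#' @return A `weekly_menu`: an integer matrix with one row per day, three
#'   columns, in canonical form.
#' @examples
#' canonicalize_menu(list(c(9, 7, 8), c(3, 1, 2)))
#' @export
canonicalize_menu <- function(days) {
  if (is.list(days)) {
    stopifnot(all(lengths(days) == 3L))
    days <- do.call(rbind, lapply(days, as.integer))
  }
  days <- matrix(as.integer(days), ncol = 3L)
  if (anyNA(days)) stop("menu contains missing dish ids", call. = FALSE)
  if (anyDuplicated(as.vector(days))) {
    stop("menu repeats a dish id; weekly menus must be partitions (each dish served exactly once)",
         call. = FALSE)
  }
  sorted <- t(apply(days, 1L, sort))
  sorted <- sorted[order(sorted[, 1L]), , drop = FALSE]
  dimnames(sorted) <- list(paste0("day", seq_len(nrow(sorted))),
                           c("dish1", "dish2", "dish3"))
  structure(sorted, class = c("weekly_menu", class(sorted)))
}

#' @rdname canonicalize_menu
#' @export
weekly_menu <- canonicalize_menu

#' @export
print.weekly_menu <- function(x, ...) {
  cat(sprintf("<weekly_menu> %d days x 3 dishes\n", nrow(x)))
  print(unclass(x))
  invisible(x)
}

#' Count feasible weekly menus by closed-form combinatorics
#'
#' Counts the partitions of `n_veg + n_meat` dishes into `n_days` unordered
#' triples with at least `min_vegetarian_per_day` vegetarian dishes per
#' triple, without enumerating. Labelled-day assignments are summed over all
#' per-day vegetarian-count compositions `(v_1, ..., v_d)` (multinomial
#' coefficients for distributing the vegetarian and meat dishes), then
#' divided by `n_days!` because the triples of a partition are distinct and
#' unordered. Serves as the independent oracle for [enumerate_menus()].
#'
#' @param n_veg,n_meat Numbers of vegetarian and meat dishes
#'   (`n_veg + n_meat` must equal `3 * n_days`).
#' @param n_days Number of days.
#' @param constraint A [menu_constraint()].
#' @return The exact count (double; 0 when the constraint is infeasible).
#' @examples
#' count_menus(5, 10, 5, menu_constraint(0))  # 1,401,400
#' count_menus(5, 10, 5, menu_constraint(1))  # 113,400
#' count_menus(6, 9, 5, menu_constraint(1))   # 340,200
#' @export
count_menus <- function(n_veg, n_meat, n_days = 5L,
                        constraint = menu_constraint()) {
  stopifnot(inherits(constraint, "menu_constraint"))
  n_veg <- as.integer(n_veg); n_meat <- as.integer(n_meat)
  n_days <- as.integer(n_days)
  if (n_veg + n_meat != 3L * n_days) {
    stop("n_veg + n_meat must equal 3 * n_days", call. = FALSE)
  }
  lo <- constraint$min_vegetarian_per_day
  comps <- veg_compositions(n_veg, n_days, lo)
  if (length(comps) == 0L) return(0)
  ordered <- sum(vapply(comps, function(v) {
    m <- 3L - v
    exp(lfactorial(n_veg) - sum(lfactorial(v)) +
        lfactorial(n_meat) - sum(lfactorial(m)))
  }, numeric(1L)))
  round(ordered / factorial(n_days))
}

# all ordered integer vectors (v_1..v_d), lo <= v_j <= 3, sum = total
veg_compositions <- function(total, d, lo) {
  if (d == 0L) {
    if (total == 0L) return(list(integer(0L))) else return(list())
  }
  out <- list()
  for (v in lo:3L) {
    rest_min <- lo * (d - 1L); rest_max <- 3L * (d - 1L)
    rest <- total - v
    if (rest < rest_min || rest > rest_max) next
    for (tail in veg_compositions(rest, d - 1L, lo)) {
      out[[length(out) + 1L]] <- c(v, tail)
    }
  }
  out
}

#' Enumerate every feasible weekly menu
#'
#' Exhaustively generates all partitions of the dish set into `n_days`
#' unordered days of three dishes, keeping those with at least
#' `min_vegetarian_per_day` vegetarian dishes on every day. Each partition is
#' produced exactly once, already in canonical form, in lexicographic order
#' of the flattened canonical form (so the stream is deterministic and
#' diff-stable). With 15 dishes this is 1,401,400 menus unconstrained,
#' 113,400 for 5 vegetarian + 10 meat dishes at minimum 1 per day, and
#' 340,200 for 6 vegetarian + 9 meat.
#'
#' The enumeration is anchor-based and level-wise vectorized: the day
#' containing the smallest unused dish is completed by every pair of larger
#' remaining dishes, which visits each unordered partition exactly once.
#'
#' @param dishes Dish table (`dish_id`, `vegetarian`); row count must be
#'   `3 * n_days`.
#' @param constraint A [menu_constraint()].
#' @param n_days Number of days (default `nrow(dishes) / 3`).
#' @return An integer matrix with one menu per row and `3 * n_days` columns
#'   (`day1_1, day1_2, day1_3, day2_1, ...`), each row a flattened canonical
#'   [weekly_menu()].
#' @export
enumerate_menus <- function(dishes, constraint = menu_constraint(),
                            n_days = nrow(dishes) %/% 3L) {
  stopifnot(inherits(constraint, "menu_constraint"))
  n <- nrow(dishes)
  n_days <- as.integer(n_days)
  if (n != 3L * n_days || n %% 3L != 0L) {
    stop(sprintf("dish count (%d) must equal 3 x n_days (%d)", n, n_days),
         call. = FALSE)
  }
  if (anyDuplicated(dishes$dish_id)) {
    stop("dish ids must be unique", call. = FALSE)
  }
  ord <- order(dishes$dish_id)
  ids <- dishes$dish_id[ord]
  veg <- as.integer(dishes$vegetarian[ord])
  min_veg <- constraint$min_vegetarian_per_day
  n_veg <- sum(veg)
  if (min_veg * n_days > n_veg) {
    stop(sprintf("constraint infeasible: %d vegetarian dishes required (%d per day x %d days) but only %d available",
                 min_veg * n_days, min_veg, n_days, n_veg), call. = FALSE)
  }

  # positions 1..n into the sorted id vector; part grows 3 columns per level
  part <- matrix(integer(0L), nrow = 1L, ncol = 0L)
  rem <- matrix(seq_len(n), nrow = 1L)
  for (level in seq_len(n_days)) {
    m <- ncol(rem)
    k_pairs <- utils::combn(seq.int(2L, m), 2L)   # position pairs, lex order
    K <- ncol(k_pairs)
    n_part <- nrow(part)
    ri <- rep(seq_len(n_part), each = K)          # parent row index
    ti <- rep(seq_len(K), times = n_part)         # pair-template index
    a <- rem[ri, 1L]
    b <- rem[cbind(ri, k_pairs[1L, ti])]
    c_ <- rem[cbind(ri, k_pairs[2L, ti])]
    keep <- (veg[a] + veg[b] + veg[c_]) >= min_veg
    if (!any(keep)) {
      out <- matrix(integer(0L), nrow = 0L, ncol = 3L * n_days)
      colnames(out) <- paste0("day", rep(seq_len(n_days), each = 3L), "_",
                              rep(1:3, n_days))
      return(out)
    }
    ri <- ri[keep]; ti <- ti[keep]
    part <- cbind(part[ri, , drop = FALSE], a[keep], b[keep], c_[keep])
    if (level < n_days) {
      keep_pos <- t(apply(k_pairs, 2L, function(p) setdiff(seq.int(2L, m), p)))
      cols <- keep_pos[ti, , drop = FALSE]
      n_new <- length(ri)
      rem <- matrix(rem[cbind(rep(ri, times = m - 3L), as.vector(cols))],
                    nrow = n_new)
    }
  }
  out <- matrix(ids[part], nrow = nrow(part))
  colnames(out) <- paste0("day", rep(seq_len(n_days), each = 3L), "_",
                          rep(1:3, n_days))
  out
}

# one row of an enumerate_menus() matrix -> weekly_menu
menu_from_row <- function(row) {
  canonicalize_menu(matrix(as.integer(row), ncol = 3L, byrow = TRUE))
}

#' Sample a baseline weekly menu
#'
#' Builds a constraint-satisfying baseline (the "starting menu" role played
#' by the catering provider's original menu): each day gets at least
#' `min_vegetarian_per_day` vegetarian dishes, any surplus vegetarian dishes
#' are spread one per day, and the remaining slots are filled with meat
#' dishes, all under a deterministic shuffle driven by `seed`.
#'
#' @param dishes Dish table.
#' @param constraint A [menu_constraint()].
#' @param seed Integer seed for the shuffle.
#' @param n_days Number of days.
#' @return A canonical [weekly_menu()].
#' @export
generate_baseline_menu <- function(dishes, constraint = menu_constraint(),
                                   seed = 1L, n_days = nrow(dishes) %/% 3L) {
  stopifnot(nrow(dishes) == 3L * n_days)
  min_veg <- constraint$min_vegetarian_per_day
  veg_ids <- dishes$dish_id[dishes$vegetarian]
  meat_ids <- dishes$dish_id[!dishes$vegetarian]
  if (length(veg_ids) < min_veg * n_days) {
    stop("constraint infeasible: not enough vegetarian dishes for the baseline",
         call. = FALSE)
  }
  with_stage_seed(seed, "baseline", {
    veg_ids <- sample(veg_ids)
    meat_ids <- sample(meat_ids)
    n_veg_day <- rep(min_veg, n_days)
    surplus <- length(veg_ids) - min_veg * n_days
    if (surplus > 0L) {
      bump <- sample.int(n_days, surplus %% n_days)
      n_veg_day <- n_veg_day + surplus %/% n_days
      n_veg_day[bump] <- n_veg_day[bump] + 1L
    }
    if (any(n_veg_day > 3L)) {
      stop("cannot place all vegetarian dishes with 3 slots per day",
           call. = FALSE)
    }
    days <- vector("list", n_days)
    vi <- 0L; mi <- 0L
    for (d in seq_len(n_days)) {
      nv <- n_veg_day[d]
      days[[d]] <- c(if (nv > 0L) veg_ids[vi + seq_len(nv)],
                     meat_ids[mi + seq_len(3L - nv)])
      vi <- vi + nv; mi <- mi + 3L - nv
    }
    canonicalize_menu(days)
  })
}

# check a weekly_menu against the dish set and constraint
check_menu <- function(menu, dishes, constraint = NULL) {
  ids <- sort(as.vector(unclass(menu)))
  want <- sort(dishes$dish_id)
  if (length(ids) != length(want) || any(ids != want)) {
    stop("menu does not partition the site's dish set", call. = FALSE)
  }
  if (!is.null(constraint)) {
    veg <- dishes$vegetarian[match(menu, dishes$dish_id)]
    dim(veg) <- dim(menu)
    per_day <- rowSums(veg)
    if (any(per_day < constraint$min_vegetarian_per_day)) {
      stop(sprintf("menu violates the vegetarian constraint on day(s) %s",
                   paste(which(per_day < constraint$min_vegetarian_per_day),
                         collapse = ", ")), call. = FALSE)
    }
  }
  invisible(menu)
}
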