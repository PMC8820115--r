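#' Draw synthetic flock rosters from a pool of other birds
#'
#' Builds `n_sim` pseudo-flocks, each a uniform without-replacement sample of
#' `length(real_flock_members)` individuals from `pool` (birds belonging to
#' other flocks). Rosters are drawn independently of one another, so the same
#' individual may appear in several rosters — mirroring the possibility that
#' distinct observed flocks contained the same bird. Deterministic given
#' `seed`; the global RNG state is left untouched.
#'
#' @param real_flock_members Character/integer ids of the real flock.
#' @param pool Ids of candidate birds from other flocks; must be disjoint
#'   from the real flock and at least as large as it.
#' @param n_sim Number of synthetic flocks (default 10).
#' @param seed Optional integer seed.
#' @return List of `n_sim` id vectors, each of the real flock's size.
#' @export
build_synthetic_flocks <- function(real_flock_members, pool, n_sim = 10, seed = NULL) {
  if (n_sim < 1) rlang::abort("`n_sim` must be at least 1.")
  if (!length(real_flock_members)) rlang::abort("Real flock is empty.")
  if (length(intersect(real_flock_members, pool))) {
    rlang::abort("`pool` must be disjoint from the real flock.")
  }
  size <- length(real_flock_members)
  if (length(pool) < size) {
    rlang::abort("`pool` must be at least as large as the real flock.")
  }
  draw <- function() replicate(n_sim, sample(pool, size), simplify = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Monte-Carlo pseudoreplication test for one flock
#'
#' Tests whether a real flock's laterality indices differ from those of
#' synthetic flocks of the same size assembled from birds of other flocks.
#' Because all individuals within a real flock are known to be distinct,
#' while the same bird could in principle have been observed in two
#' different flocks, a significant difference would flag repeated-sampling
#' (pseudoreplication) bias; a non-significant omnibus Kruskal-Wallis H
#' across the real flock and `n_sim` synthetic flocks is evidence that
#' repeated sampling does not drive the lateralization results.
#'
#' @param li_tbl Data frame with columns `bird_id`, `flock_id`, `li` (one
#'   row per bird). Restrict it to one food type before calling: LI
#'   direction differs by food, so pooling foods would confound the null.
#' @param flock Id of the real flock to test.
#' @param n_sim Number of synthetic flocks (default 10).
#' @param seed Optional integer seed for roster draws.
#' @return A `flock_mc_result` list: `real_flock_id`, `n_members`, `n_sim`,
#'   `seed`, `kw` (`lat_test` over the `n_sim + 1` groups) and
#'   `sim_flock_rosters` (for audit).
#' @export
flock_pseudoreplication_test <- function(li_tbl, flock, n_sim = 10, seed = NULL) {
  need <- c("bird_id", "flock_id", "li")
  if (!all(need %in% names(li_tbl))) {
    rlang::abort("`li_tbl` needs columns bird_id, flock_id, li.")
  }
  li_tbl <- tibble::as_tibble(li_tbl)
  if (anyDuplicated(li_tbl$bird_id)) rlang::abort("Duplicate bird_id in `li_tbl`.")
  real <- li_tbl$bird_id[li_tbl$flock_id == flock]
  if (!length(real)) rlang::abort("Flock not found or empty.")
  pool <- li_tbl$bird_id[li_tbl$flock_id != flock]
  rosters <- build_synthetic_flocks(real, pool, n_sim = n_sim, seed = seed)
  li_of <- stats::setNames(li_tbl$li, li_tbl$bird_id)
  groups <- c(list(unname(li_of[real])), lapply(rosters, function(r) unname(li_of[r])))
  kw <- tryCatch(kruskal_wallis(groups), error = function(e) {
    rlang::abort(
      sprintf("Kruskal-Wallis degenerate for flock %s: %s", flock, conditionMessage(e)),
      parent = e
    )
  })
  structure(
    list(
      real_flock_id = flock, n_members = length(real), n_sim = n_sim,
      seed = seed, kw = kw, sim_flock_rosters = rosters
    ),
    class = "flock_mc_result"
  )
}

#' @export
print.flock_mc_result <- function(x, ...) {
  cat(sprintf(
    "Flock pseudoreplication test: flock %s (%d members) vs %d synthetic flocks\n  H = %.3f, p = %.4g\n",
    x$real_flock_id, x$n_members, x$n_sim, x$kw$statistic, x$kw$p_value
  ))
  invisible(x)
}

#' @method tidy flock_mc_result
#' @export
tidy.flock_mc_result <- function(x, ...) {
  dplyr::mutate(tidy.lat_test(x$kw),
    real_flock_id = as.character(x$real_flock_id),
    n_members = x$n_members, n_sim = x$n_sim, .before = 1
  )
}

#' Run the pseudoreplication test over every flock of a classified table
#'
#' Convenience wrapper applying [flock_pseudoreplication_test()] to each
#' flock (within each food type) large enough to test, with per-flock seeds
#' derived deterministically from `seed`.
#'
#' @param classified Output of [classify_birds()] with `flock_id` (and
#'   optionally `food_type`) columns; excluded birds are ignored.
#' @param n_sim Synthetic flocks per real flock.
#' @param seed Integer master seed.
#' @param min_members Smallest flock size tested (default 2).
#' @return Tibble with one row per tested flock (tidied Kruskal-Wallis
#'   results plus `food_type`).
#' @export
flock_mc_all <- function(classified, n_sim = 10, seed = 1L, min_members = 2L) {
  cl <- tibble::as_tibble(classified)
  if (!"food_type" %in% names(cl)) cl$food_type <- "all"
  cl <- cl[cl$classification != "EXCLUDED" & !is.na(cl$li), ]
  out <- cl |>
    dplyr::group_by(.data$food_type) |>
    dplyr::group_map(function(d, key) {
      flocks <- d |>
        dplyr::count(.data$flock_id) |>
        dplyr::filter(.data$n >= min_members, .data$n <= sum(.data$n) - .data$n)
      if (!nrow(flocks)) {
        return(NULL)
      }
      seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(flocks)))
      purrr::map2(flocks$flock_id, seeds, function(f, s) {
        res <- tryCatch(
          flock_pseudoreplication_test(d, f, n_sim = n_sim, seed = s),
          error = function(e) NULL
        )
        if (is.null(res)) {
          return(NULL)
        }
        dplyr::mutate(tidy(res), food_type = key$food_type, .before = 1)
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  out
}
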