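#' Laterality index
#'
#' `LI = (L - R) / (L + R)` over counts of left- and right-eye monocular
#' inspections. Ranges from -1 (fully right-eyed) to +1 (fully left-eyed);
#' positive values indicate a left-side bias. Vectorised.
#'
#' @param n_left,n_right Non-negative integer counts of left- and right-eye
#'   monocular inspections.
#' @return Numeric vector of laterality indices in \[-1, 1\].
#' @examples
#' laterality_index(15, 5)
#' @export
laterality_index <- function(n_left, n_right) {
  if (any(n_left < 0, na.rm = TRUE) || any(n_right < 0, na.rm = TRUE)) {
    rlang::abort("Counts must be non-negative.")
  }
  tot <- n_left + n_right
  if (any(tot == 0, na.rm = TRUE)) {
    rlang::abort("`n_left + n_right` must be at least 1.")
  }
  (n_left - n_right) / tot
}

#' Classify individual eye preference from per-bird inspection counts
#'
#' Takes a data frame of per-bird summaries (one row per bird, with columns
#' `n_left` and `n_right`; see [summarize_birds()]) and classifies each bird
#' as `LEFT`, `RIGHT`, `NONE` (analyzable but not lateralized) or `EXCLUDED`.
#' A bird is `EXCLUDED` when it has fewer than `min_inspections` monocular
#' inspections (threshold inclusive: `n_left + n_right >= min_inspections`
#' analyzable) or when its visit was `interrupted` by a social interaction.
#' Otherwise the left count is tested against a fair-eye null and the bird is
#' lateralized toward its majority eye when the two-tailed p-value is below
#' `alpha`.
#'
#' @param birds Data frame with columns `bird_id`, `n_left`, `n_right`;
#'   optional `interrupted` (logical or 0/1) and any grouping columns
#'   (`food_type`, `site_id`, ...), which are passed through.
#' @param alpha Two-tailed significance level for the per-bird test.
#' @param min_inspections Minimum monocular inspections for analyzability
#'   (inclusive).
#' @param method `"exact"` (default) classifies on the exact tail-doubled
#'   binomial p-value, appropriate at per-bird sample sizes of 15-60;
#'   `"z"` uses the continuity-corrected normal approximation. Both the z
#'   statistic and the exact p are reported regardless.
#' @return The input tibble plus columns `n_inspections`, `li`, `abs_li`,
#'   `z`, `p_exact`, `p_z`, `p_value` (the one used), `classification`
#'   (factor LEFT/RIGHT/NONE/EXCLUDED) and `excluded_reason`
#'   (NA, "below_min_inspections" or "interrupted").
#' @examples
#' birds <- tibble::tibble(bird_id = c("a", "b"), n_left = c(18, 9), n_right = c(3, 10))
#' classify_birds(birds)
#' @export
classify_birds <- function(birds, alpha = 0.05, min_inspections = 15,
                           method = c("exact", "z")) {
  method <- rlang::arg_match(method)
  if (!all(c("bird_id", "n_left", "n_right") %in% names(birds))) {
    rlang::abort("`birds` needs columns bird_id, n_left, n_right.")
  }
  if (alpha <= 0 || alpha > 1) rlang::abort("`alpha` must be in (0, 1].")
  b <- tibble::as_tibble(birds)
  if (!"interrupted" %in% names(b)) b$interrupted <- FALSE
  n_insp <- b$n_left + b$n_right
  li <- ifelse(n_insp > 0, (b$n_left - b$n_right) / n_insp, NA_real_)
  z <- ifelse(n_insp > 0, binom_z_stat(b$n_left, pmax(n_insp, 1)), NA_real_)
  p_exact <- ifelse(n_insp > 0, binom_exact_p(b$n_left, pmax(n_insp, 1)), NA_real_)
  p_z <- 2 * stats::pnorm(-abs(z))
  p_used <- if (method == "exact") p_exact else p_z
  interrupted <- as.logical(b$interrupted) %in% TRUE
  excluded <- interrupted | n_insp < min_inspections
  cls <- dplyr::case_when(
    excluded ~ "EXCLUDED",
    p_used < alpha & b$n_left > b$n_right ~ "LEFT",
    p_used < alpha & b$n_right > b$n_left ~ "RIGHT",
    .default = "NONE"
  )
  b |>
    dplyr::mutate(
      n_inspections = n_insp,
      li = li,
      abs_li = abs(li),
      z = z,
      p_exact = p_exact,
      p_z = p_z,
      p_value = p_used,
      classification = factor(cls, levels = c("LEFT", "RIGHT", "NONE", "EXCLUDED")),
      excluded_reason = dplyr::case_when(
        interrupted ~ "interrupted",
        n_insp < min_inspections ~ "below_min_inspections",
        .default = NA_character_
      )
    )
}

# Distribution-free 95% CI for the median via binomial order statistics.
# Reported descriptively; the bounds are conservative at small n.
median_with_ci <- function(x, conf = 0.95) {
  x <- sort(unname(x))
  n <- length(x)
  if (n == 0L) {
    return(c(median = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
  }
  a <- (1 - conf) / 2
  lo <- max(1L, stats::qbinom(a, n, 0.5))
  hi <- min(n, stats::qbinom(1 - a, n, 0.5) + 1L)
  c(median = stats::median(x), ci_lo = x[lo], ci_hi = x[hi])
}

#' Population-level lateralization summary and tests
#'
#' Aggregates classified birds (see [classify_birds()]) per food type and
#' runs the three population-level tests: (1) prevalence — are significantly
#' more birds lateralized than expected under a fair 50:50 split
#' (continuity-corrected binomial z on lateralized vs analyzable)?
#' (2) direction — among lateralized birds, does the majority eye dominate
#' (binomial z on the majority count)? (3) location — is the distribution of
#' per-bird laterality indices shifted from 0 (one-sample Wilcoxon signed
#' rank)? Also reports the median number of monocular inspections per
#' analyzable bird with a distribution-free 95% CI.
#'
#' @param classified Output of [classify_birds()]; a `food_type` column, if
#'   present, defines one report row per food type.
#' @param li_include Which birds contribute LI values to the Wilcoxon test:
#'   `"analyzable"` (default; every non-excluded bird, including NONE) or
#'   `"lateralized"` (LEFT/RIGHT only).
#' @return A tibble (class `population_report`) with one row per food type:
#'   counts (`n_analyzable`, `n_left_pref`, `n_right_pref`, `n_none`),
#'   statistics and p-values for the three tests (`lateralized_z`,
#'   `lateralized_p`, `direction`, `direction_z`, `direction_p`, `li_w`,
#'   `li_p`), the LI median, inspection medians with CI, and a `tests`
#'   list-column holding the full `lat_test` objects. The direction test is
#'   omitted (NA) when no bird is lateralized.
#' @export
population_analysis <- function(classified, li_include = c("analyzable", "lateralized")) {
  li_include <- rlang::arg_match(li_include)
  cl <- tibble::as_tibble(classified)
  if (!"food_type" %in% names(cl)) cl$food_type <- "all"
  if (!"classification" %in% names(cl)) {
    rlang::abort("`classified` must come from classify_birds().")
  }
  one <- function(d, ft) {
    d <- d[d$classification != "EXCLUDED", ]
    if (!nrow(d)) rlang::abort("Need at least one non-excluded bird.")
    n_an <- nrow(d)
    n_l <- sum(d$classification == "LEFT")
    n_r <- sum(d$classification == "RIGHT")
    n_lat <- n_l + n_r
    lat_test <- binom_z_test(n_lat, n_an)
    if (n_lat > 0) {
      direction <- if (n_l >= n_r) "LEFT" else "RIGHT"
      dir_test <- binom_z_test(max(n_l, n_r), n_lat)
    } else {
      direction <- NA_character_
      dir_test <- NULL
    }
    li_vals <- if (li_include == "analyzable") {
      d$li
    } else {
      d$li[d$classification %in% c("LEFT", "RIGHT")]
    }
    li_test <- tryCatch(wilcoxon_signed_rank(li_vals, 0), error = function(e) NULL)
    mci <- median_with_ci(d$n_inspections)
    tibble::tibble(
      food_type = ft,
      n_analyzable = n_an,
      n_left_pref = n_l,
      n_right_pref = n_r,
      n_none = n_an - n_lat,
      prop_lateralized = n_lat / n_an,
      lateralized_z = lat_test$statistic,
      lateralized_p = lat_test$p_value,
      direction = direction,
      direction_z = if (is.null(dir_test)) NA_real_ else dir_test$statistic,
      direction_p = if (is.null(dir_test)) NA_real_ else dir_test$p_value,
      li_median = stats::median(li_vals),
      li_w = if (is.null(li_test)) NA_real_ else li_test$statistic,
      li_p = if (is.null(li_test)) NA_real_ else li_test$p_value,
      median_inspections = mci[["median"]],
      inspections_ci_lo = mci[["ci_lo"]],
      inspections_ci_hi = mci[["ci_hi"]],
      tests = list(list(
        lateralized_vs_total = lat_test,
        direction_among_lateralized = dir_test,
        li_location = li_test
      ))
    )
  }
  out <- cl |>
    dplyr::group_by(.data$food_type) |>
    dplyr::group_map(~ one(.x, .y$food_type)) |>
    dplyr::bind_rows()
  class(out) <- c("population_report", class(out))
  out
}

#' Compare strength of lateralization (ABS-LI) between two groups
#'
#' Mann-Whitney test on the absolute laterality indices of two samples of
#' birds, e.g. the two food types. Strength is direction-free, so this asks
#' whether one feeding context elicits stronger eye preferences than the
#' other.
#'
#' @param abs_li_a,abs_li_b Numeric vectors of ABS-LI values in \[0, 1\].
#' @return A `lat_test` object (see [mann_whitney_u()]).
#' @export
strength_comparison <- function(abs_li_a, abs_li_b) {
  if (any(c(abs_li_a, abs_li_b) < 0, na.rm = TRUE) ||
    any(c(abs_li_a, abs_li_b) > 1, na.rm = TRUE)) {
    rlang::abort("ABS-LI values must lie in [0, 1].")
  }
  mann_whitney_u(abs_li_a, abs_li_b)
}

#' @method tidy population_report
#' @export
tidy.population_report <- function(x, ...) {
  x |>
    dplyr::select("food_type", "tests") |>
    dplyr::mutate(tests = purrr::map(.data$tests, function(tl) {
      purrr::imap(tl, function(t, nm) {
        if (is.null(t)) {
          return(NULL)
        }
        dplyr::mutate(tidy.lat_test(t), analysis = nm, .before = 1)
      }) |>
        dplyr::bind_rows()
    })) |>
    tidyr::unnest("tests")
}
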