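#' Active feeding time after freeze exclusion
#'
#' Time a bird actually spent feeding during a visit: the span from landing
#' to the last peck, minus every "freeze" (motionless pause without food
#' searching) strictly longer than `freeze_threshold_s` seconds. Freezes at
#' or below the threshold are ordinary pauses and are kept.
#'
#' @param t_land_s Landing time (seconds from session start).
#' @param t_peck_s Peck times for the visit, non-decreasing, all
#'   `>= t_land_s`.
#' @param freeze_before_s Freeze duration preceding each peck (0 if none);
#'   recycled if scalar.
#' @param freeze_threshold_s Exclusion threshold in seconds (default 5;
#'   strictly-greater rule).
#' @return Active feeding time in seconds.
#' @examples
#' active_feeding_time(0, c(10, 60, 120), c(0, 10, 0)) # one 10 s freeze
#' @export
active_feeding_time <- function(t_land_s, t_peck_s, freeze_before_s = 0,
                                freeze_threshold_s = 5) {
  if (!length(t_peck_s)) rlang::abort("`t_peck_s` must be non-empty.")
  if (is.unsorted(t_peck_s)) rlang::abort("Peck timestamps must be ordered.")
  if (any(t_peck_s < t_land_s)) rlang::abort("Pecks cannot precede landing.")
  freeze_before_s <- rep_len(freeze_before_s, length(t_peck_s))
  if (any(freeze_before_s < 0)) rlang::abort("Freeze durations must be >= 0.")
  total <- max(t_peck_s) - t_land_s
  frozen <- sum(freeze_before_s[freeze_before_s > freeze_threshold_s])
  total - frozen
}

#' Ingestion rate
#'
#' Food items consumed per minute of active feeding time:
#' `60 * n_success / active_time_s`. Vectorised.
#'
#' @param n_success Number of successful pecks (items swallowed).
#' @param active_time_s Active feeding time in seconds (must be positive).
#' @return Items per minute.
#' @examples
#' ingestion_rate(30, 600)
#' @export
ingestion_rate <- function(n_success, active_time_s) {
  if (any(active_time_s <= 0, na.rm = TRUE)) {
    rlang::abort("`active_time_s` must be positive.")
  }
  if (any(n_success < 0, na.rm = TRUE)) rlang::abort("`n_success` must be >= 0.")
  60 * n_success / active_time_s
}

#' Compare per-bird pecking accuracy between lateralized and non-lateralized birds
#'
#' Mann-Whitney test on per-bird success proportions (successful pecks over
#' total lateral pecks). If every bird in both groups has the same
#' proportion — e.g. a food on which no pecking errors occur at all — the
#' comparison is degenerate and p = 1 is returned rather than an error, so a
#' no-error food type is handled gracefully.
#'
#' @param success_props_lateralized,success_props_nonlateralized Per-bird
#'   success proportions in \[0, 1\].
#' @return A `lat_test` object.
#' @export
accuracy_comparison <- function(success_props_lateralized,
                                success_props_nonlateralized) {
  props <- c(success_props_lateralized, success_props_nonlateralized)
  if (any(props < 0 | props > 1, na.rm = TRUE)) {
    rlang::abort("Success proportions must lie in [0, 1].")
  }
  mann_whitney_u(success_props_lateralized, success_props_nonlateralized)
}

#' Eye-conditional error analysis under a balanced fixed-error design
#'
#' For each lateralized bird, takes its pecking errors in chronological
#' order, keeps exactly the first `n_errors_cap` (birds with fewer errors
#' are dropped — the balanced design), and splits them by the eye used for
#' the monocular inspection before the errant peck: after the bird's
#' preferred eye vs after its non-preferred eye. Errors with no monocular
#' inspection are excluded from both tallies. Within each
#' preference-direction group (LEFT-preferring, RIGHT-preferring birds) a
#' Wilcoxon matched-pairs signed-rank test compares the per-bird counts; the
#' statistic is oriented so that `W > 0` means more errors after the
#' non-preferred eye.
#'
#' With `compare = "rates"` the paired quantities are instead per-bird error
#' rates per inspection under each eye (requires `n_left`/`n_right`
#' inspection counts in `errors`), which adjusts for unequal exposure of the
#' two eyes.
#'
#' @param errors Data frame of error events only (pecks not followed by
#'   swallowing) for LEFT/RIGHT-classified birds, with columns `bird_id`,
#'   `preference` ("LEFT"/"RIGHT"), `inspection_eye` ("L"/"R"/"NONE") and
#'   `t_peck_s` (or any sortable order column named `t_peck_s`).
#' @param n_errors_cap Errors per bird in the balanced design (default 6).
#' @param compare `"counts"` (default) or `"rates"`.
#' @param inspections Optional data frame `bird_id`, `n_left`, `n_right`
#'   needed for `compare = "rates"`.
#' @return A `balanced_error_result` list: `breakdown` (per-bird tibble with
#'   `errors_after_preferred_eye`, `errors_after_nonpreferred_eye`,
#'   `errors_used`), `tests` (named list with `LEFT` and `RIGHT` group
#'   `lat_test`s, `NULL` with an omission marker when a group has no
#'   qualifying birds), `n_dropped` and `cap`.
#' @export
balanced_error_analysis <- function(errors, n_errors_cap = 6,
                                    compare = c("counts", "rates"),
                                    inspections = NULL) {
  compare <- rlang::arg_match(compare)
  need <- c("bird_id", "preference", "inspection_eye", "t_peck_s")
  if (!all(need %in% names(errors))) {
    rlang::abort(paste("`errors` needs columns:", paste(need, collapse = ", ")))
  }
  e <- tibble::as_tibble(errors) |>
    dplyr::filter(.data$preference %in% c("LEFT", "RIGHT")) |>
    dplyr::arrange(.data$bird_id, .data$t_peck_s)
  counts <- e |> dplyr::count(.data$bird_id, name = "n_errors_total")
  qualifying <- counts$bird_id[counts$n_errors_total >= n_errors_cap]
  n_dropped <- sum(counts$n_errors_total < n_errors_cap)
  breakdown <- e |>
    dplyr::filter(.data$bird_id %in% qualifying) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::slice_head(n = n_errors_cap) |>
    dplyr::summarise(
      preference = dplyr::first(.data$preference),
      errors_used = dplyr::n(),
      errors_after_preferred_eye = sum(
        (.data$preference == "LEFT" & .data$inspection_eye == "L") |
          (.data$preference == "RIGHT" & .data$inspection_eye == "R")
      ),
      errors_after_nonpreferred_eye = sum(
        (.data$preference == "LEFT" & .data$inspection_eye == "R") |
          (.data$preference == "RIGHT" & .data$inspection_eye == "L")
      ),
      .groups = "drop"
    )
  if (compare == "rates") {
    if (is.null(inspections)) {
      rlang::abort("`inspections` is required for compare = \"rates\".")
    }
    breakdown <- breakdown |>
      dplyr::left_join(
        dplyr::select(tibble::as_tibble(inspections), "bird_id", "n_left", "n_right"),
        by = "bird_id"
      )
  }
  group_test <- function(d) {
    if (!nrow(d)) {
      return(NULL)
    }
    diffs <- if (compare == "counts") {
      d$errors_after_nonpreferred_eye - d$errors_after_preferred_eye
    } else {
      n_pref <- ifelse(d$preference == "LEFT", d$n_left, d$n_right)
      n_nonpref <- ifelse(d$preference == "LEFT", d$n_right, d$n_left)
      d$errors_after_nonpreferred_eye / pmax(n_nonpref, 1) -
        d$errors_after_preferred_eye / pmax(n_pref, 1)
    }
    tryCatch(wilcoxon_signed_rank(diffs, 0), error = function(err) NULL)
  }
  tests <- list(
    LEFT = group_test(breakdown[breakdown$preference == "LEFT", ]),
    RIGHT = group_test(breakdown[breakdown$preference == "RIGHT", ])
  )
  structure(
    list(
      breakdown = breakdown, tests = tests,
      n_dropped = n_dropped, cap = n_errors_cap, compare = compare
    ),
    class = "balanced_error_result"
  )
}

#' @export
print.balanced_error_result <- function(x, ...) {
  cat(sprintf(
    "Balanced %d-error eye-conditional analysis (%s): %d birds, %d dropped\n",
    x$cap, x$compare, nrow(x$breakdown), x$n_dropped
  ))
  for (g in c("LEFT", "RIGHT")) {
    if (is.null(x$tests[[g]])) {
      cat(sprintf("  %s-preferring: test omitted (no qualifying birds)\n", g))
    } else {
      t <- x$tests[[g]]
      cat(sprintf(
        "  %s-preferring: W = %.1f, p = %.4g (n = %d)\n",
        g, t$statistic, t$p_value, t$n
      ))
    }
  }
  invisible(x)
}

#' @method tidy balanced_error_result
#' @export
tidy.balanced_error_result <- function(x, ...) {
  purrr::imap(x$tests, function(t, nm) {
    if (is.null(t)) {
      return(tibble::tibble(preference = nm, omitted = TRUE))
    }
    dplyr::mutate(tidy.lat_test(t), preference = nm, omitted = FALSE, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Compare feeding efficiency or latency between bird groups
#'
#' Mann-Whitney test on a per-bird efficiency metric between two groups
#' defined by lateralization: lateralized (LEFT or RIGHT) vs non-lateralized
#' (NONE), or left- vs right-lateralized.
#'
#' @param records Data frame with a `classification` column
#'   (LEFT/RIGHT/NONE) and the metric column.
#' @param grouping `"lat_vs_nonlat"` or `"left_vs_right"`.
#' @param metric Name of the numeric column to compare, e.g.
#'   `"ingestion_rate"` or `"latency_s"`.
#' @return A `lat_test` object; the first sample is the lateralized (or
#'   LEFT) group.
#' @export
efficiency_comparison <- function(records,
                                  grouping = c("lat_vs_nonlat", "left_vs_right"),
                                  metric = "ingestion_rate") {
  grouping <- rlang::arg_match(grouping)
  r <- tibble::as_tibble(records)
  if (!metric %in% names(r)) rlang::abort(sprintf("No column `%s`.", metric))
  if (!"classification" %in% names(r)) rlang::abort("Need `classification` column.")
  cls <- as.character(r$classification)
  if (grouping == "lat_vs_nonlat") {
    a <- r[[metric]][cls %in% c("LEFT", "RIGHT")]
    b <- r[[metric]][cls == "NONE"]
  } else {
    a <- r[[metric]][cls == "LEFT"]
    b <- r[[metric]][cls == "RIGHT"]
  }
  mann_whitney_u(a, b)
}
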