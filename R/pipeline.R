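event_cols <- c(
  "site_id", "tree_id", "flock_id", "bird_id", "food_type",
  "t_land_s", "t_peck_s", "inspection_eye", "success",
  "freeze_before_s", "interrupted"
)

#' Analysis configuration
#'
#' Bundles the analysis thresholds: per-test significance level, the minimum
#' number of monocular inspections for a bird to be analyzable, the number
#' of errors per bird in the balanced accuracy design, the freeze-exclusion
#' threshold, the number of synthetic flocks in the pseudoreplication test,
#' and the seed that makes the whole run deterministic.
#'
#' @param alpha Two-tailed significance level (default 0.05).
#' @param min_inspections Analyzability threshold, inclusive (default 15).
#' @param n_errors_cap Errors per bird in the balanced design (default 6).
#' @param freeze_threshold_s Freeze exclusion threshold in seconds
#'   (default 5).
#' @param n_sim_flocks Synthetic flocks per real flock (default 10).
#' @param seed Integer seed for the Monte-Carlo components.
#' @param classify_method `"exact"` or `"z"`, see [classify_birds()].
#' @param li_include Which birds enter the population LI test, see
#'   [population_analysis()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, min_inspections = 15L,
                            n_errors_cap = 6L, freeze_threshold_s = 5,
                            n_sim_flocks = 10L, seed = 1L,
                            classify_method = c("exact", "z"),
                            li_include = c("analyzable", "lateralized")) {
  stopifnot(
    alpha > 0, alpha <= 1, min_inspections >= 1, n_errors_cap >= 1,
    freeze_threshold_s > 0, n_sim_flocks >= 1
  )
  structure(
    list(
      alpha = alpha, min_inspections = as.integer(min_inspections),
      n_errors_cap = as.integer(n_errors_cap),
      freeze_threshold_s = freeze_threshold_s,
      n_sim_flocks = as.integer(n_sim_flocks), seed = as.integer(seed),
      classify_method = rlang::arg_match(classify_method),
      li_include = rlang::arg_match(li_include)
    ),
    class = "analysis_config"
  )
}

#' Read and write peck-event tables
#'
#' The canonical event CSV is UTF-8, comma-separated, with a header row and
#' the columns `site_id, tree_id, flock_id, bird_id, food_type, t_land_s,
#' t_peck_s, inspection_eye (L/R/NONE), success (0/1), freeze_before_s,
#' interrupted (0/1)`; times are seconds as decimals. Reading validates the
#' schema.
#'
#' @param path File path.
#' @param events Event tibble (e.g. from [simulate_pecks()]).
#' @return `read_peck_events()` returns a validated tibble;
#'   `write_peck_events()` returns `path` invisibly.
#' @export
read_peck_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_events(ev)
  ev
}

#' @rdname read_peck_events
#' @export
write_peck_events <- function(events, path) {
  readr::write_csv(dplyr::select(events, dplyr::all_of(event_cols)), path, progress = FALSE)
  invisible(path)
}

validate_events <- function(events) {
  missing <- setdiff(event_cols, names(events))
  if (length(missing)) {
    rlang::abort(paste("Event table lacks columns:", paste(missing, collapse = ", ")))
  }
  bad_eye <- !events$inspection_eye %in% c("L", "R", "NONE")
  if (any(bad_eye)) {
    rlang::abort(sprintf(
      "Invalid inspection_eye at row %d.", which(bad_eye)[1]
    ))
  }
  if (!all(events$success %in% c(0, 1))) {
    rlang::abort("`success` must be 0/1.")
  }
  neg <- events$t_peck_s < events$t_land_s
  if (any(neg)) {
    rlang::abort(sprintf(
      "Negative latency (t_peck_s < t_land_s) at row %d.", which(neg)[1]
    ))
  }
  if (any(events$freeze_before_s < 0)) {
    rlang::abort("`freeze_before_s` must be >= 0.")
  }
  invisible(events)
}

#' Summarize peck events into one row per bird visit
#'
#' Aggregates a validated event table into per-visit summaries: counts of
#' left-eye, right-eye and non-lateral pecks, successes, latency from
#' landing to first peck, and active feeding time (total visit span minus
#' freezes above the exclusion threshold, via [active_feeding_time()]).
#' A visit is one (bird, tree, landing) episode, so a bird recorded on two
#' trees yields two rows. Interrupted visits are flagged; downstream
#' analyses drop them.
#'
#' @param events Event tibble with the canonical schema.
#' @param config An [analysis_config()].
#' @return Tibble with one row per visit: ids, `food_type`, `n_left`,
#'   `n_right`, `n_nonlateral`, `n_pecks`, `n_success`, `latency_s`,
#'   `active_time_s`, `interrupted`.
#' @export
summarize_birds <- function(events, config = analysis_config()) {
  if (!nrow(events)) {
    rlang::warn("Empty event table; returning an empty summary.")
    return(tibble::tibble(
      site_id = character(), tree_id = character(), flock_id = character(),
      bird_id = character(), food_type = character(),
      n_left = integer(), n_right = integer(), n_nonlateral = integer(),
      n_pecks = integer(), n_success = integer(),
      latency_s = numeric(), active_time_s = numeric(), interrupted = logical()
    ))
  }
  validate_events(events)
  unsorted <- tibble::as_tibble(events) |>
    dplyr::group_by(.data$bird_id, .data$tree_id, .data$t_land_s) |>
    dplyr::summarise(bad = is.unsorted(.data$t_peck_s), .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(unsorted)) {
    rlang::abort(sprintf(
      "Unordered peck timestamps for bird %s.", unsorted$bird_id[1]
    ))
  }
  tibble::as_tibble(events) |>
    dplyr::group_by(
      .data$site_id, .data$tree_id, .data$flock_id, .data$bird_id,
      .data$food_type, .data$t_land_s
    ) |>
    dplyr::summarise(
      n_left = sum(.data$inspection_eye == "L"),
      n_right = sum(.data$inspection_eye == "R"),
      n_nonlateral = sum(.data$inspection_eye == "NONE"),
      n_pecks = dplyr::n(),
      n_success = sum(.data$success),
      latency_s = min(.data$t_peck_s) - .data$t_land_s[1],
      active_time_s = active_feeding_time(
        .data$t_land_s[1], .data$t_peck_s, .data$freeze_before_s,
        config$freeze_threshold_s
      ),
      interrupted = any(.data$interrupted == 1),
      .groups = "drop"
    ) |>
    dplyr::select(-"t_land_s")
}

stage <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(omitted = TRUE, reason = conditionMessage(e)),
      class = "omitted_stage"
    )
  })
}

is_omitted <- function(x) inherits(x, "omitted_stage") || is.null(x)

#' Run the full lateralization analysis pipeline
#'
#' Composes every stage on a raw event table: per-visit summaries,
#' per-bird eye-preference classification, population-level prevalence /
#' direction / LI-location tests per food type, strength (ABS-LI)
#' comparison between food types, accuracy and balanced eye-conditional
#' error analyses (for foods on which errors occur; a no-error food yields
#' an omission marker rather than a failure), ingestion-rate and latency
#' efficiency comparisons, the Monte-Carlo flock pseudoreplication test for
#' every testable flock, and Kruskal-Wallis grouping checks of LI across
#' trees and flocks. Any stage hitting a degenerate input is recorded as
#' omitted (with the reason) without aborting the others. Deterministic
#' given `config$seed`.
#'
#' @param events Event tibble with the canonical schema.
#' @param config An [analysis_config()].
#' @return A `lat_report` list with components `summaries`, `classified`,
#'   `population`, `strength`, `accuracy`, `balanced_errors`, `efficiency`,
#'   `flock_mc`, `grouping_checks`, `exclusions` and `config`.
#' @export
run_full_analysis <- function(events, config = analysis_config()) {
  summaries <- summarize_birds(events, config)
  n_input <- nrow(summaries)
  analyzable_input <- summaries |> dplyr::filter(!.data$interrupted)
  classified <- classify_birds(
    analyzable_input,
    alpha = config$alpha, min_inspections = config$min_inspections,
    method = config$classify_method
  )
  population <- stage(population_analysis(classified, li_include = config$li_include))
  foods <- unique(classified$food_type)
  analyzable <- classified |> dplyr::filter(.data$classification != "EXCLUDED")

  strength <- if (length(foods) >= 2) {
    stage(strength_comparison(
      analyzable$abs_li[analyzable$food_type == foods[1]],
      analyzable$abs_li[analyzable$food_type == foods[2]]
    ))
  } else {
    structure(list(omitted = TRUE, reason = "single food type"), class = "omitted_stage")
  }

  per_food <- function(f) {
    d <- analyzable |> dplyr::filter(.data$food_type == f)
    d <- d |> dplyr::mutate(
      ingestion_rate = 60 * .data$n_success / .data$active_time_s
    )
    # success proportion over lateral pecks is not recoverable from the
    # count columns alone, so recompute it from the events
    ev_f <- events |>
      dplyr::filter(.data$food_type == f, .data$bird_id %in% d$bird_id)
    lat_succ <- ev_f |>
      dplyr::filter(.data$inspection_eye != "NONE") |>
      dplyr::group_by(.data$bird_id) |>
      dplyr::summarise(success_prop = mean(.data$success), .groups = "drop")
    d <- d |> dplyr::left_join(lat_succ, by = "bird_id")
    accuracy <- stage({
      t <- accuracy_comparison(
        d$success_prop[d$classification %in% c("LEFT", "RIGHT")],
        d$success_prop[d$classification == "NONE"]
      )
      if (length(unique(stats::na.omit(d$success_prop))) == 1L) {
        structure(list(omitted = TRUE, reason = "no pecking errors recorded"),
          class = "omitted_stage"
        )
      } else {
        t
      }
    })
    errors <- ev_f |>
      dplyr::filter(.data$success == 0) |>
      dplyr::inner_join(
        d |>
          dplyr::filter(.data$classification %in% c("LEFT", "RIGHT")) |>
          dplyr::transmute(.data$bird_id, preference = as.character(.data$classification)),
        by = "bird_id"
      )
    balanced <- if (nrow(errors)) {
      stage(balanced_error_analysis(errors, n_errors_cap = config$n_errors_cap))
    } else {
      structure(list(omitted = TRUE, reason = "no pecking errors recorded"),
        class = "omitted_stage"
      )
    }
    efficiency <- list(
      ingestion_lat_vs_nonlat = stage(efficiency_comparison(d, "lat_vs_nonlat", "ingestion_rate")),
      ingestion_left_vs_right = stage(efficiency_comparison(d, "left_vs_right", "ingestion_rate")),
      latency_lat_vs_nonlat = stage(efficiency_comparison(d, "lat_vs_nonlat", "latency_s"))
    )
    grouping <- list(
      li_by_tree = stage(kruskal_wallis(d$li, d$tree_id)),
      li_by_flock = stage(kruskal_wallis(d$li, d$flock_id))
    )
    list(
      accuracy = accuracy, balanced_errors = balanced,
      efficiency = efficiency, grouping_checks = grouping, metrics = d
    )
  }
  by_food <- stats::setNames(lapply(foods, per_food), foods)
  flock_mc <- stage(flock_mc_all(classified, n_sim = config$n_sim_flocks, seed = config$seed))

  exclusions <- tibble::tibble(
    n_input = n_input,
    n_interrupted = n_input - nrow(analyzable_input),
    n_below_min_inspections = sum(classified$excluded_reason %in% "below_min_inspections"),
    n_analyzed = nrow(analyzable)
  )
  stopifnot(exclusions$n_input ==
    exclusions$n_analyzed + exclusions$n_interrupted + exclusions$n_below_min_inspections)

  structure(
    list(
      summaries = summaries, classified = classified, population = population,
      strength = strength,
      accuracy = purrr::map(by_food, "accuracy"),
      balanced_errors = purrr::map(by_food, "balanced_errors"),
      efficiency = purrr::map(by_food, "efficiency"),
      grouping_checks = purrr::map(by_food, "grouping_checks"),
      metrics = purrr::map(by_food, "metrics"),
      flock_mc = flock_mc, exclusions = exclusions, config = config
    ),
    class = "lat_report"
  )
}

#' @export
print.lat_report <- function(x, ...) {
  cat("Lateralization analysis report\n")
  cat(sprintf(
    "  %d visits in, %d analyzable birds (%d interrupted, %d below threshold)\n",
    x$exclusions$n_input, x$exclusions$n_analyzed,
    x$exclusions$n_interrupted, x$exclusions$n_below_min_inspections
  ))
  if (!is_omitted(x$population)) print(dplyr::select(
    x$population, "food_type", "n_analyzable", "n_left_pref", "n_right_pref",
    "n_none", "lateralized_z", "direction", "direction_z", "li_median"
  ))
  invisible(x)
}

#' @method tidy lat_report
#' @export
tidy.lat_report <- function(x, ...) {
  rows <- list()
  add <- function(analysis, food, t) {
    if (is_omitted(t)) {
      return()
    }
    rows[[length(rows) + 1]] <<- dplyr::mutate(
      tidy.lat_test(t),
      analysis = analysis, food_type = food, .before = 1
    )
  }
  if (!is_omitted(x$population)) {
    pop <- tidy(x$population)
    rows[[length(rows) + 1]] <- pop |>
      dplyr::rename(food = "food_type") |>
      dplyr::transmute(
        analysis = .data$analysis, food_type = .data$food,
        method = .data$method, statistic = .data$statistic,
        p_value = .data$p_value, n = .data$n, exact = .data$exact
      )
  }
  add("strength_abs_li", "both", x$strength)
  for (f in names(x$accuracy)) add("accuracy_lat_vs_nonlat", f, x$accuracy[[f]])
  for (f in names(x$balanced_errors)) {
    be <- x$balanced_errors[[f]]
    if (is_omitted(be)) next
    for (g in c("LEFT", "RIGHT")) {
      add(paste0("balanced_errors_", tolower(g)), f, be$tests[[g]])
    }
  }
  for (f in names(x$efficiency)) {
    for (nm in names(x$efficiency[[f]])) add(nm, f, x$efficiency[[f]][[nm]])
  }
  for (f in names(x$grouping_checks)) {
    for (nm in names(x$grouping_checks[[f]])) add(nm, f, x$grouping_checks[[f]][[nm]])
  }
  out <- dplyr::bind_rows(rows)
  if (!is_omitted(x$flock_mc) && nrow(x$flock_mc)) {
    out <- dplyr::bind_rows(out, x$flock_mc |>
      dplyr::transmute(
        analysis = paste0("flock_mc_", .data$real_flock_id),
        food_type = .data$food_type, method = .data$method,
        statistic = .data$statistic, p_value = .data$p_value,
        n = .data$n, exact = .data$exact
      ))
  }
  out
}

#' @method glance lat_report
#' @export
glance.lat_report <- function(x, ...) {
  dplyr::bind_cols(
    x$exclusions,
    tibble::tibble(
      n_foods = length(x$accuracy),
      n_flock_mc = if (is_omitted(x$flock_mc)) 0L else nrow(x$flock_mc)
    )
  )
}

report_record <- function(x) {
  if (is_omitted(x)) {
    return(list(omitted = TRUE, reason = if (is.null(x$reason)) "unavailable" else x$reason))
  }
  if (inherits(x, "lat_test")) {
    return(lat_test_record(x))
  }
  x
}

#' Serialize a report to JSON
#'
#' Writes a `lat_report` as a structured JSON document (schema shipped at
#' `system.file("extdata", "report-schema.json", package = "pecklat")`).
#' Every test appears as a `{method, statistic, p_value, n, exact}` record;
#' omitted stages appear as `{omitted: true, reason: ...}`; synthetic flock
#' rosters are not included here (retrieve them from
#' [flock_pseudoreplication_test()] directly when auditing).
#'
#' @param report A `lat_report`.
#' @param path Output path; directories are created as needed.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  pop <- if (is_omitted(report$population)) {
    report_record(report$population)
  } else {
    report$population |>
      dplyr::select(-"tests") |>
      purrr::transpose()
  }
  doc <- list(
    exclusions = as.list(report$exclusions),
    population = pop,
    strength = report_record(report$strength),
    accuracy = purrr::map(report$accuracy, report_record),
    balanced_errors = purrr::map(report$balanced_errors, function(be) {
      if (is_omitted(be)) {
        return(report_record(be))
      }
      list(
        n_birds = nrow(be$breakdown), n_dropped = be$n_dropped, cap = be$cap,
        tests = purrr::map(be$tests, lat_test_record)
      )
    }),
    efficiency = purrr::map(report$efficiency, ~ purrr::map(.x, report_record)),
    grouping_checks = purrr::map(report$grouping_checks, ~ purrr::map(.x, report_record)),
    flock_mc = if (is_omitted(report$flock_mc)) {
      report_record(report$flock_mc)
    } else {
      purrr::transpose(dplyr::select(report$flock_mc, -dplyr::any_of("se")))
    },
    config = unclass(report$config)
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Check a report JSON document against the shipped schema
#'
#' Minimal structural validation: verifies that the document has every
#' required top-level section and that each test record carries the required
#' fields with the right types, following the JSON schema shipped with the
#' package.
#'
#' @param path Path to a JSON report written by [report_to_json()].
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report_json <- function(path) {
  doc <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "pecklat")
  )
  required <- unlist(schema$required)
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    rlang::abort(paste("Report lacks sections:", paste(missing, collapse = ", ")))
  }
  check_test <- function(t, where) {
    if (isTRUE(t$omitted)) {
      return(invisible(TRUE))
    }
    need <- c("method", "statistic", "p_value", "n", "exact")
    miss <- setdiff(need, names(t))
    if (length(miss)) {
      rlang::abort(sprintf("Test record %s lacks %s.", where, paste(miss, collapse = ", ")))
    }
    if (!is.numeric(t$statistic) || !is.numeric(t$p_value) ||
      t$p_value < 0 || t$p_value > 1) {
      rlang::abort(sprintf("Test record %s has invalid statistic/p_value.", where))
    }
    invisible(TRUE)
  }
  check_test(doc$strength, "strength")
  purrr::iwalk(doc$accuracy, ~ check_test(.x, paste0("accuracy/", .y)))
  purrr::iwalk(doc$efficiency, function(effs, f) {
    purrr::iwalk(effs, ~ check_test(.x, paste0("efficiency/", f, "/", .y)))
  })
  invisible(TRUE)
}
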