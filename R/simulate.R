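#' Configuration for the synthetic peck-event generator
#'
#' Assembles and validates the full parameterization of
#' [simulate_pecks()]. Defaults emulate the structure of field observations
#' of wild frugivorous pigeons feeding on two food types at two study sites:
#' three focal trees per food type per site, flocks of mean 6 (SD 3,
#' truncated at 1) birds, a median of about 20 monocular inspections per
#' bird with enough over-dispersion that some birds fall below the
#' 15-inspection analyzability threshold, eye-conditional pecking-error
#' probabilities (none for the fig-like food, on which essentially every
#' peck succeeds), lognormal feeding latencies (mean 8.7 s vs 15.0 s by
#' food), and occasional freezes, some exceeding the 5 s exclusion
#' threshold.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_sites,trees_per_food_per_site,n_flocks_per_tree Study layout.
#' @param food_types Character vector of food type labels.
#' @param flock_size_mean,flock_size_sd Normal flock-size model, rounded and
#'   truncated at 1.
#' @param mixture Named list (per food type) of length-3 simplex weights
#'   `c(L = , R = , N = )`: probabilities that a bird is left-preferring,
#'   right-preferring, or non-lateralized.
#' @param pref_strength Per-bird probability q of inspecting with the
#'   preferred eye, in \[0.5, 1\]. Either a single number or length-2
#'   `c(shape1, shape2)` Beta parameters (rescaled to \[0.5, 1\]).
#'   Non-lateralized birds use q = 0.5.
#' @param inspections_mean,inspections_size Negative-binomial model (mean,
#'   dispersion size) for monocular inspections per bird; over-dispersed so
#'   that some birds are below the analyzability threshold, truncated at 1.
#' @param p_monocular Probability a peck is preceded by a monocular
#'   inspection; non-inspected pecks are "non-lateral".
#' @param error_probs Named list (per food type) of
#'   `c(pref = , nonpref = , nonlateral = )` pecking-error probabilities by
#'   inspection condition. Non-lateralized birds use the mean of `pref` and
#'   `nonpref` for monocular pecks.
#' @param latency_mean_s Named per-food mean latency (landing to first peck,
#'   seconds); lognormal with `latency_sdlog`.
#' @param latency_sdlog Log-scale SD of the latency distribution.
#' @param nonlateralized_latency_mult Multiplier on mean latency for
#'   non-lateralized birds (> 1 means they start feeding later).
#' @param inter_peck_mean_s Named per-food mean inter-peck interval
#'   (seconds); lognormal with `inter_peck_sdlog`.
#' @param inter_peck_sdlog Log-scale SD of inter-peck intervals.
#' @param nonlateralized_interval_mult Multiplier on mean inter-peck
#'   interval for non-lateralized birds (> 1 means slower feeding, hence a
#'   lower ingestion rate).
#' @param freeze_prob Probability any given peck is preceded by a freeze.
#' @param freeze_mean_s Mean of the exponential freeze-duration
#'   distribution; with the default 4 s roughly 29% of freezes exceed the
#'   5 s exclusion threshold.
#' @param markov_persistence Probability rho that a monocular inspection
#'   repeats the previous inspection's eye instead of being drawn afresh
#'   (serial autocorrelation of eye choice); 0 (default) gives i.i.d.
#'   choices.
#' @param p_interrupted Probability a bird's visit is interrupted by a
#'   social interaction (such birds are flagged and excluded downstream).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 2L,
                       trees_per_food_per_site = 3L,
                       n_flocks_per_tree = 3L,
                       food_types = c("mahua_flower", "fig_fruit"),
                       flock_size_mean = 6,
                       flock_size_sd = 3,
                       mixture = list(
                         mahua_flower = c(L = 0.50, R = 0.20, N = 0.30),
                         fig_fruit = c(L = 0.20, R = 0.55, N = 0.25)
                       ),
                       pref_strength = 0.8,
                       inspections_mean = 20,
                       inspections_size = 10,
                       p_monocular = 0.6,
                       error_probs = list(
                         mahua_flower = c(pref = 0.12, nonpref = 0.60, nonlateral = 0.36),
                         fig_fruit = c(pref = 0, nonpref = 0, nonlateral = 0)
                       ),
                       latency_mean_s = c(mahua_flower = 8.7, fig_fruit = 15.0),
                       latency_sdlog = 0.5,
                       nonlateralized_latency_mult = 1.8,
                       inter_peck_mean_s = c(mahua_flower = 10, fig_fruit = 8),
                       inter_peck_sdlog = 0.6,
                       nonlateralized_interval_mult = 1.4,
                       freeze_prob = 0.08,
                       freeze_mean_s = 4,
                       markov_persistence = 0,
                       p_interrupted = 0.02) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$food_types) >= 1,
    cfg$n_sites >= 1, cfg$trees_per_food_per_site >= 1, cfg$n_flocks_per_tree >= 1,
    cfg$flock_size_mean > 0, cfg$flock_size_sd >= 0,
    cfg$inspections_mean > 0, cfg$inspections_size > 0
  )
  probs <- c(
    cfg$p_monocular, cfg$freeze_prob, cfg$p_interrupted,
    cfg$markov_persistence
  )
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("Config probabilities must lie in [0, 1].")
  }
  for (ft in cfg$food_types) {
    m <- cfg$mixture[[ft]]
    if (is.null(m) || length(m) != 3 || any(m < 0) || abs(sum(m) - 1) > 1e-8) {
      rlang::abort(sprintf("`mixture` for %s must be a length-3 simplex.", ft))
    }
    e <- cfg$error_probs[[ft]]
    if (is.null(e) || length(e) != 3 || any(e < 0 | e > 1)) {
      rlang::abort(sprintf("`error_probs` for %s must be 3 probabilities.", ft))
    }
    if (is.na(cfg$latency_mean_s[ft]) || is.na(cfg$inter_peck_mean_s[ft])) {
      rlang::abort(sprintf("Missing latency/interval mean for %s.", ft))
    }
  }
  q <- cfg$pref_strength
  if (length(q) == 1) {
    if (q < 0.5 || q > 1) rlang::abort("`pref_strength` must lie in [0.5, 1].")
  } else if (length(q) != 2 || any(q <= 0)) {
    rlang::abort("`pref_strength` must be one probability or 2 Beta shapes.")
  }
  invisible(cfg)
}

rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Latent bird-level table: layout, class, q, inspection counts.
simulate_birds_latent <- function(cfg) {
  layout <- tidyr::expand_grid(
    food_type = cfg$food_types,
    site = seq_len(cfg$n_sites),
    tree = seq_len(cfg$trees_per_food_per_site),
    flock = seq_len(cfg$n_flocks_per_tree)
  ) |>
    dplyr::mutate(
      site_id = sprintf("S%d", .data$site),
      tree_id = sprintf("%s_%s_T%d", .data$site_id, .data$food_type, .data$tree),
      flock_id = sprintf("%s_F%d", .data$tree_id, .data$flock),
      flock_size = pmax(1L, as.integer(round(stats::rnorm(
        dplyr::n(), cfg$flock_size_mean, cfg$flock_size_sd
      )))),
      flock_arrival_s = stats::runif(dplyr::n(), 0, 10800)
    )
  birds <- layout |>
    tidyr::uncount(.data$flock_size) |>
    dplyr::mutate(bird_id = sprintf("B%05d", dplyr::row_number()))
  n <- nrow(birds)
  cls <- character(n)
  for (ft in cfg$food_types) {
    idx <- birds$food_type == ft
    cls[idx] <- sample(c("LEFT", "RIGHT", "NONE"), sum(idx),
      replace = TRUE, prob = cfg$mixture[[ft]]
    )
  }
  q <- if (length(cfg$pref_strength) == 1) {
    rep(cfg$pref_strength, n)
  } else {
    0.5 + 0.5 * stats::rbeta(n, cfg$pref_strength[1], cfg$pref_strength[2])
  }
  q[cls == "NONE"] <- 0.5
  n_insp <- pmax(1L, stats::rnbinom(n, mu = cfg$inspections_mean, size = cfg$inspections_size))
  mu_nl <- n_insp * (1 - cfg$p_monocular) / max(cfg$p_monocular, 1e-9)
  n_nonlat <- if (cfg$p_monocular >= 1) {
    rep(0L, n)
  } else {
    stats::rnbinom(n, mu = mu_nl, size = cfg$inspections_size)
  }
  ep <- do.call(rbind, cfg$error_probs[birds$food_type])
  birds |>
    dplyr::mutate(
      class = cls, q = q,
      n_inspections = as.integer(n_insp),
      n_nonlateral = as.integer(n_nonlat),
      e_pref = ep[, "pref"], e_nonpref = ep[, "nonpref"],
      e_nonlateral = ep[, "nonlateral"],
      interrupted = stats::rbinom(dplyr::n(), 1, cfg$p_interrupted),
      t_land_s = .data$flock_arrival_s + stats::runif(dplyr::n(), 0, 60)
    )
}

simulate_bird_events <- function(bird, cfg) {
  n_mono <- bird$n_inspections
  n_total <- n_mono + bird$n_nonlateral
  mono_pos <- sort(sample.int(n_total, n_mono))
  eye <- rep("NONE", n_total)
  pref_eye <- switch(bird$class,
    LEFT = "L",
    RIGHT = "R",
    sample(c("L", "R"), 1)
  )
  nonpref_eye <- if (pref_eye == "L") "R" else "L"
  base <- ifelse(stats::runif(n_mono) < bird$q, pref_eye, nonpref_eye)
  if (cfg$markov_persistence > 0 && n_mono > 1) {
    keep <- stats::runif(n_mono) < cfg$markov_persistence
    for (i in 2:n_mono) if (keep[i]) base[i] <- base[i - 1]
  }
  eye[mono_pos] <- base
  e_mono_pref <- if (bird$class == "NONE") {
    (bird$e_pref + bird$e_nonpref) / 2
  } else {
    bird$e_pref
  }
  e_mono_nonpref <- if (bird$class == "NONE") e_mono_pref else bird$e_nonpref
  p_err <- dplyr::case_when(
    eye == "NONE" ~ bird$e_nonlateral,
    eye == pref_eye ~ e_mono_pref,
    .default = e_mono_nonpref
  )
  success <- stats::rbinom(n_total, 1, 1 - p_err)
  mult <- if (bird$class == "NONE") cfg$nonlateralized_latency_mult else 1
  latency <- rlnorm_mean(1, cfg$latency_mean_s[[bird$food_type]] * mult, cfg$latency_sdlog)
  imult <- if (bird$class == "NONE") cfg$nonlateralized_interval_mult else 1
  gaps <- rlnorm_mean(n_total, cfg$inter_peck_mean_s[[bird$food_type]] * imult, cfg$inter_peck_sdlog)
  gaps[1] <- latency
  freeze <- ifelse(
    stats::rbinom(n_total, 1, cfg$freeze_prob) == 1,
    stats::rexp(n_total, 1 / cfg$freeze_mean_s), 0
  )
  t_peck <- bird$t_land_s + cumsum(gaps + freeze)
  tibble::tibble(
    site_id = bird$site_id, tree_id = bird$tree_id, flock_id = bird$flock_id,
    bird_id = bird$bird_id, food_type = bird$food_type,
    t_land_s = bird$t_land_s, t_peck_s = t_peck,
    inspection_eye = eye, success = as.integer(success),
    freeze_before_s = freeze, interrupted = bird$interrupted
  )
}

#' Simulate a peck-event table
#'
#' Generates one row per observed peck across the whole synthetic study
#' (sites, trees, flocks, birds), with the columns of the canonical event
#' schema: `site_id`, `tree_id`, `flock_id`, `bird_id`, `food_type`,
#' `t_land_s`, `t_peck_s`, `inspection_eye` (L/R/NONE), `success` (0/1),
#' `freeze_before_s`, `interrupted` (0/1). Each bird's latent lateralization
#' class is drawn from the food type's mixture; each monocular inspection
#' uses the preferred eye with probability q; each peck succeeds with
#' probability `1 - e(condition)`; timestamps come from the latency,
#' inter-peck-interval and freeze processes. Fully deterministic given
#' `config$seed`; the global RNG state is untouched.
#'
#' @param config A [sim_config()] object.
#' @return Tibble of peck events (per-bird times strictly increasing), with
#'   the latent per-bird parameters attached as the `"ground_truth"`
#'   attribute (see [ground_truth()]).
#' @examples
#' ev <- simulate_pecks(sim_config(seed = 7, n_flocks_per_tree = 1))
#' dplyr::count(ev, food_type, inspection_eye)
#' @export
simulate_pecks <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, {
    birds <- simulate_birds_latent(config)
    events <- birds |>
      purrr::transpose() |>
      purrr::map(simulate_bird_events, cfg = config) |>
      dplyr::bind_rows()
  })
  truth <- birds |>
    dplyr::select(
      "bird_id", "food_type", "site_id", "tree_id", "flock_id",
      "class", "q", "n_inspections", "n_nonlateral",
      "e_pref", "e_nonpref", "e_nonlateral", "interrupted"
    )
  attr(events, "ground_truth") <- truth
  events
}

#' Latent ground-truth labels of a simulated event table
#'
#' Returns the per-bird latent parameters (lateralization class, preferred-eye
#' probability q, error probabilities, true inspection counts) that generated
#' a [simulate_pecks()] table. Intended only for parameter-recovery and
#' calibration testing; the analysis functions never consume it.
#'
#' @param x A table produced by [simulate_pecks()] (dplyr operations preserve
#'   the attribute).
#' @return Tibble with one row per simulated bird.
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "ground_truth", exact = TRUE)
  if (is.null(gt)) {
    rlang::abort("`x` carries no ground truth; was it made by simulate_pecks()?")
  }
  gt
}

#' Simulate per-bird inspection summaries directly
#'
#' Lightweight bird-level generator for calibration and power studies that
#' do not need event-level structure: draws each bird's lateralization class
#' from `mixture`, then its left-eye inspection count from
#' Binomial(n, p) with p = q, 1 - q or 0.5 for LEFT, RIGHT and NONE birds.
#'
#' @param n_birds Number of birds.
#' @param mixture Length-3 simplex `c(L = , R = , N = )`.
#' @param q Preferred-eye probability for lateralized birds.
#' @param inspections Monocular inspections per bird; scalar or length
#'   `n_birds`.
#' @param seed Optional integer seed (global RNG untouched).
#' @return Tibble `bird_id`, `true_class`, `n_inspections`, `n_left`,
#'   `n_right`.
#' @examples
#' simulate_bird_summaries(5, c(L = 1, R = 0, N = 0), q = 1, inspections = 20, seed = 1)
#' @export
simulate_bird_summaries <- function(n_birds, mixture = c(L = 0.5, R = 0.2, N = 0.3),
                                    q = 0.8, inspections = 30, seed = NULL) {
  if (length(mixture) != 3 || any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    rlang::abort("`mixture` must be a length-3 simplex.")
  }
  if (q < 0.5 || q > 1) rlang::abort("`q` must lie in [0.5, 1].")
  n_insp <- rep_len(as.integer(inspections), n_birds)
  if (any(n_insp < 1)) rlang::abort("`inspections` must be >= 1.")
  draw <- function() {
    cls <- sample(c("LEFT", "RIGHT", "NONE"), n_birds, replace = TRUE, prob = mixture)
    p_left <- dplyr::case_when(cls == "LEFT" ~ q, cls == "RIGHT" ~ 1 - q, .default = 0.5)
    tibble::tibble(
      bird_id = sprintf("B%05d", seq_len(n_birds)),
      true_class = cls,
      n_inspections = n_insp,
      n_left = stats::rbinom(n_birds, n_insp, p_left)
    ) |>
      dplyr::mutate(n_right = .data$n_inspections - .data$n_left)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
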