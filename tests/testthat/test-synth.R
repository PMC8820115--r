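test_that("simulation is byte-identical given the seed and leaves the global RNG alone", {
  cfg <- sim_config(seed = 5, n_flocks_per_tree = 1)
  withr::with_seed(123, invisible(stats::runif(1)))
  before <- .Random.seed
  ev1 <- simulate_pecks(cfg)
  expect_identical(.Random.seed, before)
  ev2 <- simulate_pecks(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_peck_events(ev1, f1)
  write_peck_events(ev2, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  expect_false(identical(
    simulate_pecks(sim_config(seed = 6, n_flocks_per_tree = 1))$t_peck_s,
    ev1$t_peck_s
  ))
})

test_that("event tables satisfy the schema invariants", {
  ev <- simulate_pecks(sim_config(seed = 8, n_flocks_per_tree = 1))
  expect_true(all(ev$t_peck_s > ev$t_land_s))
  expect_true(all(ev$inspection_eye %in% c("L", "R", "NONE")))
  expect_true(all(ev$success %in% 0:1))
  increasing <- ev |>
    dplyr::group_by(bird_id) |>
    dplyr::summarise(ok = all(diff(t_peck_s) > 0), .groups = "drop")
  expect_true(all(increasing$ok))
})

test_that("ground truth aligns with birds, is seed-stable, and survives row shuffles", {
  cfg <- sim_config(seed = 31, n_flocks_per_tree = 1)
  ev <- simulate_pecks(cfg)
  gt <- ground_truth(ev)
  expect_setequal(gt$bird_id, unique(ev$bird_id))
  expect_false(anyDuplicated(gt$bird_id) > 0)
  gt2 <- ground_truth(simulate_pecks(cfg))
  expect_identical(gt, gt2)
  shuffled <- dplyr::slice_sample(ev, n = nrow(ev))
  expect_identical(ground_truth(shuffled), gt)
  expect_error(ground_truth(tibble::tibble(a = 1)), "ground truth")
})

test_that("per-bird eye-choice frequencies converge to q (law of large numbers)", {
  cfg <- sim_config(
    seed = 77, n_sites = 1, trees_per_food_per_site = 1, n_flocks_per_tree = 1,
    food_types = "mahua_flower",
    mixture = list(mahua_flower = c(L = 1, R = 0, N = 0)),
    pref_strength = 0.8, inspections_mean = 10000, inspections_size = 1e6,
    p_interrupted = 0
  )
  ev <- simulate_pecks(cfg)
  freq <- ev |>
    dplyr::filter(inspection_eye != "NONE") |>
    dplyr::group_by(bird_id) |>
    dplyr::summarise(f_left = mean(inspection_eye == "L"), n = dplyr::n())
  expect_true(all(freq$n > 5000))
  expect_true(all(abs(freq$f_left - 0.8) < 0.02))
})

test_that("flock sizes track the configured mean and SD", {
  cfg <- sim_config(
    seed = 99, n_sites = 2, trees_per_food_per_site = 5, n_flocks_per_tree = 30,
    food_types = "mahua_flower", inspections_mean = 2, inspections_size = 5
  )
  gt <- ground_truth(simulate_pecks(cfg))
  sizes <- dplyr::count(gt, flock_id)$n
  expect_gt(length(sizes), 250)
  # rounding + truncation at 1 shift the moments slightly; generous bands
  expect_lt(abs(mean(sizes) - 6), 0.5)
  expect_lt(abs(stats::sd(sizes) - 3), 0.5)
})

test_that("a pure-left population with perfect preference is fully recovered", {
  cfg <- sim_config(
    seed = 14, n_sites = 1, trees_per_food_per_site = 1, n_flocks_per_tree = 4,
    food_types = "mahua_flower",
    mixture = list(mahua_flower = c(L = 1, R = 0, N = 0)),
    pref_strength = 1, p_interrupted = 0
  )
  ev <- simulate_pecks(cfg)
  cl <- classify_birds(summarize_birds(ev))
  analyzable <- dplyr::filter(cl, classification != "EXCLUDED")
  expect_gt(nrow(analyzable), 5)
  expect_true(all(analyzable$classification == "LEFT"))
  expect_true(all(analyzable$li == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mixture = list(
    mahua_flower = c(L = 0.6, R = 0.6, N = 0.2),
    fig_fruit = c(L = 0.2, R = 0.55, N = 0.25)
  )), "simplex")
  expect_error(sim_config(pref_strength = 0.3), "0.5")
  expect_error(sim_config(p_monocular = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(error_probs = list(
    mahua_flower = c(pref = -0.1, nonpref = 0.2, nonlateral = 0.1),
    fig_fruit = c(pref = 0, nonpref = 0, nonlateral = 0)
  )), "probabilities")
})

test_that("bird-level summary generator respects the mixture and q", {
  b <- simulate_bird_summaries(2000, c(L = 0.5, R = 0.2, N = 0.3),
    q = 0.8, inspections = 40, seed = 3
  )
  expect_equal(nrow(b), 2000)
  expect_equal(b$n_left + b$n_right, rep(40L, 2000))
  prop <- table(b$true_class) / 2000
  expect_lt(abs(prop[["LEFT"]] - 0.5), 0.04)
  f_pref <- mean(b$n_left[b$true_class == "LEFT"]) / 40
  expect_lt(abs(f_pref - 0.8), 0.01)
  expect_identical(
    b,
    simulate_bird_summaries(2000, c(L = 0.5, R = 0.2, N = 0.3), 0.8, 40, seed = 3)
  )
})
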