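test_that("active feeding time excludes only freezes above the threshold", {
  expect_equal(active_feeding_time(0, c(30, 60, 120)), 120)
  expect_equal(active_feeding_time(0, c(30, 60, 120), c(0, 10, 0)), 110)
  # three 4 s freezes: at or below 5 s, all kept
  expect_equal(active_feeding_time(0, c(30, 60, 120), c(4, 4, 4)), 120)
  # boundary: exactly 5 s is kept (strictly-greater rule)
  expect_equal(active_feeding_time(0, c(30, 120), c(5, 5.01)), 120 - 5.01)
  expect_error(active_feeding_time(0, c(10, 5)), "ordered")
  expect_error(active_feeding_time(20, c(10, 30)), "precede")
})

test_that("active time never increases with freezing and ignores sub-threshold freezes", {
  withr::with_seed(77, {
    t_pecks <- cumsum(stats::runif(20, 1, 10))
    base <- active_feeding_time(0, t_pecks)
    fr <- rep(0, 20)
    prev <- base
    for (i in c(3, 8, 15)) {
      fr[i] <- 6 + stats::runif(1, 0, 10)
      cur <- active_feeding_time(0, t_pecks, fr)
      expect_lt(cur, prev)
      prev <- cur
    }
    small <- ifelse(fr > 0, fr, stats::runif(20, 0, 5))
    small[fr > 0] <- fr[fr > 0]
    expect_equal(active_feeding_time(0, t_pecks, small), prev)
  })
})

test_that("ingestion rate is items per minute and scale invariant", {
  expect_equal(ingestion_rate(30, 600), 3)
  expect_equal(ingestion_rate(0, 300), 0)
  expect_equal(ingestion_rate(60, 1200), ingestion_rate(30, 600))
  expect_error(ingestion_rate(5, 0), "positive")
})

test_that("accuracy comparison separates groups and survives the no-error case", {
  t <- accuracy_comparison(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5))
  expect_equal(t$statistic, 0)
  ident <- accuracy_comparison(c(1, 1, 1), c(1, 1, 1)) # all-success food
  expect_equal(ident$p_value, 1)
  expect_error(accuracy_comparison(numeric(), c(0.5)), "non-empty")
  expect_error(accuracy_comparison(c(1.5), c(0.5)), "0, 1")
})

test_that("balanced design keeps exactly the first cap errors and drops short birds", {
  # bird A: 9 errors, first 6 are 5 nonpref + 1 pref, last 3 all pref
  # bird B: 5 errors -> dropped
  err <- tibble::tibble(
    bird_id = c(rep("A", 9), rep("B", 5)),
    preference = "LEFT",
    inspection_eye = c("L", rep("R", 5), rep("L", 3), rep("R", 5)),
    t_peck_s = c(1:9, 1:5)
  )
  r <- balanced_error_analysis(err)
  expect_equal(nrow(r$breakdown), 1)
  expect_equal(r$n_dropped, 1)
  expect_equal(r$breakdown$errors_used, 6)
  expect_equal(r$breakdown$errors_after_preferred_eye, 1)
  expect_equal(r$breakdown$errors_after_nonpreferred_eye, 5)
  expect_true(is.null(r$tests$RIGHT))
})

test_that("errors without monocular inspection are excluded from both tallies", {
  err <- tibble::tibble(
    bird_id = "A", preference = "RIGHT",
    inspection_eye = c("NONE", "L", "NONE", "R", "L", "L"),
    t_peck_s = 1:6
  )
  r <- balanced_error_analysis(err)
  expect_equal(r$breakdown$errors_after_preferred_eye, 1) # the single R
  expect_equal(r$breakdown$errors_after_nonpreferred_eye, 3) # the three L
  expect_equal(r$breakdown$errors_used, 6)
})

test_that("results are invariant to errors appended beyond the cap", {
  withr::with_seed(88, {
    base <- make_error_events(12, p_nonpref = 0.7)
    extra <- make_error_events(12, p_nonpref = 0.1) |>
      dplyr::mutate(t_peck_s = t_peck_s + 100)
    r1 <- balanced_error_analysis(base)
    r2 <- balanced_error_analysis(dplyr::bind_rows(base, extra))
    expect_equal(r1$breakdown, r2$breakdown)
    expect_equal(r1$tests$LEFT$statistic, r2$tests$LEFT$statistic)
    expect_equal(r1$tests$LEFT$p_value, r2$tests$LEFT$p_value)
  })
})

test_that("a uniform nonpreferred-eye excess yields the maximal positive signed rank", {
  err <- purrr::map(1:8, function(i) {
    tibble::tibble(
      bird_id = sprintf("b%d", i), preference = "LEFT",
      inspection_eye = c("L", rep("R", 5)), t_peck_s = 1:6
    )
  }) |> dplyr::bind_rows()
  r <- balanced_error_analysis(err)
  # constant difference +4 for all 8 birds: W = +n(n+1)/2
  expect_equal(r$tests$LEFT$statistic, 8 * 9 / 2)
  expect_lt(r$tests$LEFT$p_value, 0.01)
})

test_that("rate-based comparison adjusts for unequal eye exposure", {
  err <- make_error_events(10, p_nonpref = 0.5)
  insp <- tibble::tibble(
    bird_id = sprintf("b%04d", 1:10), n_left = 30, n_right = 10
  )
  r <- balanced_error_analysis(err, compare = "rates", inspections = insp)
  expect_s3_class(r, "balanced_error_result")
  expect_error(balanced_error_analysis(err, compare = "rates"), "required")
})

test_that("efficiency comparison contrasts the requested groups", {
  rec <- tibble::tibble(
    bird_id = sprintf("b%d", 1:6),
    classification = c("LEFT", "LEFT", "RIGHT", "NONE", "NONE", "NONE"),
    ingestion_rate = c(3.0, 3.1, 3.2, 1.0, 1.1, 1.2),
    latency_s = c(5, 6, 7, 20, 21, 22)
  )
  t <- efficiency_comparison(rec, "lat_vs_nonlat")
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 0.1)
  t2 <- efficiency_comparison(rec, "left_vs_right")
  expect_equal(t2$n, 3)
  t3 <- efficiency_comparison(rec, "lat_vs_nonlat", metric = "latency_s")
  expect_equal(t3$statistic, 0)
  expect_error(
    efficiency_comparison(dplyr::filter(rec, classification != "NONE"), "lat_vs_nonlat"),
    "non-empty"
  )
})
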