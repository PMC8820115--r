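test_that("continuity-corrected binomial z reproduces reference prevalence and direction statistics", {
  cases <- list(
    list(k = 54, n = 74, z = 3.84),
    list(k = 33, n = 43, z = 3.35),
    list(k = 39, n = 54, z = 3.13),
    list(k = 24, n = 33, z = 2.44)
  )
  for (c in cases) {
    t <- binom_z_test(c$k, c$n)
    expect_equal(round(t$statistic, 2), c$z)
    expect_lt(t$p_value, 0.05)
    expect_false(t$exact)
  }
  balanced <- binom_z_test(37, 74)
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p_value, 1)
  expect_error(binom_z_test(0, 0), "at least 1")
  expect_error(binom_z_test(5, 3), "0 <= k <= n")
})

test_that("binomial z is antisymmetric in k vs n - k", {
  for (n in c(1, 2, 7, 20, 74)) {
    for (k in 0:n) {
      expect_equal(
        binom_z_test(k, n)$statistic, -binom_z_test(n - k, n)$statistic
      )
    }
  }
})

test_that("exact binomial p matches direct pmf-summation oracle for all n <= 25", {
  expect_equal(binom_exact_test(15, 15)$p_value, 2 * 0.5^15, tolerance = 1e-12)
  expect_equal(binom_exact_test(15, 15)$p_value, 6.1035e-05, tolerance = 1e-4)
  expect_equal(binom_exact_test(10, 20)$p_value, 1.0)
  expect_equal(binom_exact_test(1, 15)$p_value, 2 * 16 / 32768, tolerance = 1e-12)
  for (n in 1:25) {
    for (k in 0:n) {
      expect_equal(
        binom_exact_test(k, n)$p_value, oracle_binom_exact_p(k, n),
        tolerance = 1e-12
      )
    }
  }
  expect_true(binom_exact_test(3, 10)$exact)
})

test_that("wilcoxon signed rank: exact p equals sign-enumeration oracle on tie-free samples", {
  t <- wilcoxon_signed_rank(c(-2, -1, 1, 2))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 1)

  t <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(t$statistic, 6)
  expect_equal(t$p_value, 0.25)
  expect_true(t$exact)

  expect_error(wilcoxon_signed_rank(5, mu = 5), "Degenerate")

  withr::with_seed(101, {
    for (rep in 1:40) {
      n <- sample(3:8, 1)
      # distinct magnitudes with random signs: tie-free for the exact path
      x <- rand_distinct(n) * sample(c(-1, 1), n, replace = TRUE)
      t <- wilcoxon_signed_rank(x)
      o <- oracle_signed_rank(x)
      expect_equal(t$statistic, o$W)
      expect_equal(t$p_value, o$p, tolerance = 1e-12)
      # independent library cross-check on the exact path
      wt <- suppressWarnings(stats::wilcox.test(x, exact = TRUE))
      expect_equal(t$p_value, wt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("wilcoxon signed rank handles zeros and ties via the approximate path", {
  t <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3), mu = 0)
  expect_equal(t$n, 3) # zeros dropped
  tied <- wilcoxon_signed_rank(c(-2, -1, 1, 2, 5))
  expect_false(tied$exact)
  expect_gte(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
})

test_that("mann-whitney U and exact p equal the labeling-enumeration oracle", {
  t <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 2 / 20)
  expect_true(t$exact)

  # direct pairwise-count oracle: U_a = 6, U_b = 3, min = 3
  t <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))
  expect_equal(t$statistic, 3)
  expect_equal(t$statistic, oracle_mwu(c(1, 3, 5), c(2, 4, 6))$U)

  same <- mann_whitney_u(c(2, 2, 7), c(2, 2, 7))
  expect_equal(same$statistic, 9 / 2)
  expect_gt(same$p_value, 0.9)

  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")

  withr::with_seed(202, {
    for (rep in 1:40) {
      n_a <- sample(2:4, 1)
      n_b <- sample(2:4, 1)
      v <- rand_distinct(n_a + n_b)
      a <- v[seq_len(n_a)]
      b <- v[-seq_len(n_a)]
      t <- mann_whitney_u(a, b)
      o <- oracle_mwu(a, b)
      expect_equal(t$statistic, o$U)
      expect_equal(t$p_value, o$p, tolerance = 1e-12)
    }
  })
})

test_that("mann-whitney approximate path tracks the reference implementation", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      a <- sample(30, 12, replace = TRUE) # ties likely
      b <- sample(30, 15, replace = TRUE) + 3
      t <- mann_whitney_u(a, b)
      expect_false(t$exact)
      wt <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
      expect_equal(t$p_value, wt$p.value, tolerance = 0.02)
    }
  })
})

test_that("kruskal-wallis matches hand-computed H and the reference implementation", {
  t <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(t$statistic, 7.2)
  expect_equal(t$df, 2)
  expect_equal(kruskal_wallis(list(c(1, 3), c(2, 4)))$statistic, 0.6)

  # invariance under strictly increasing transforms
  g <- list(c(0.1, 0.9, 0.4), c(0.2, 0.8), c(0.5, 0.6, 0.95))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) - 1))$statistic
  expect_equal(h1, h2)

  withr::with_seed(404, {
    for (rep in 1:10) {
      x <- sample(12, 30, replace = TRUE) # heavy ties
      grp <- sample(3, 30, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(grp)) < 2) next
      t <- kruskal_wallis(x, grp)
      kt <- stats::kruskal.test(x, grp)
      expect_equal(t$statistic, unname(kt$statistic), tolerance = 1e-12)
      expect_equal(t$p_value, kt$p.value, tolerance = 1e-12)
    }
  })

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("cohens kappa: perfect, chance and reference agreement levels", {
  expect_equal(cohens_kappa(diag(c(20, 15, 15)))$statistic, 1)

  # independent margins => chance agreement, kappa = 0
  m <- outer(c(40, 40, 20), c(40, 40, 20)) / 100
  expect_equal(cohens_kappa(m)$statistic, 0, tolerance = 1e-12)

  # constructed 3x3 with Po = 0.90, Pe = 0.375 => kappa = 0.84
  path <- system.file("extdata", "rater_confusion_synthetic.csv", package = "pecklat")
  cm <- as.matrix(utils::read.csv(path))
  k <- cohens_kappa(cm)
  expect_equal(sum(cm), 100)
  expect_equal(k$percent_agreement, 90)
  expect_equal(k$pe, 0.375)
  expect_equal(k$statistic, 0.84)
  expect_gt(k$se, 0)

  expect_error(cohens_kappa(matrix(5, 1, 1)), "Degenerate")
  expect_error(cohens_kappa(matrix(1:6, 2, 3)), "square")
})

test_that("kappa is at most 1, with equality iff the matrix is diagonal", {
  withr::with_seed(505, {
    for (rep in 1:30) {
      d <- sample(2:4, 1)
      m <- matrix(stats::rpois(d * d, 3), d, d)
      if (sum(m) == 0) next
      k <- tryCatch(cohens_kappa(m)$statistic, error = function(e) NA)
      if (is.na(k)) next
      expect_lte(k, 1)
      if (sum(m) - sum(diag(m)) == 0) expect_equal(k, 1) else expect_lt(k, 1)
    }
  })
})

test_that("all p-values stay in [0, 1] under randomized-input fuzzing", {
  withr::with_seed(606, {
    for (rep in 1:50) {
      p <- c(
        binom_z_test(sample(0:30, 1), 30)$p_value,
        binom_exact_test(sample(0:17, 1), 17)$p_value,
        wilcoxon_signed_rank(stats::rnorm(sample(2:25, 1)) + 0.3)$p_value,
        mann_whitney_u(
          sample(8, sample(2:10, 1), replace = TRUE),
          sample(8, sample(2:10, 1), replace = TRUE)
        )$p_value,
        kruskal_wallis(
          stats::rnorm(20), sample(4, 20, replace = TRUE)
        )$p_value
      )
      expect_true(all(p >= 0 & p <= 1))
    }
  })
})
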