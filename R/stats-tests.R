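#' @keywords internal
new_lat_test <- function(statistic, p_value, method, n, exact, ...) {
  out <- c(
    list(
      statistic = as.numeric(statistic),
      p_value = as.numeric(p_value),
      method = method,
      n = as.integer(n),
      exact = isTRUE(exact)
    ),
    list(...)
  )
  structure(out, class = "lat_test")
}

#' @export
print.lat_test <- function(x, ...) {
  cat(sprintf(
    "<%s>  statistic = %.4g, p = %.4g, n = %d%s\n",
    x$method, x$statistic, x$p_value, x$n,
    if (x$exact) " (exact)" else ""
  ))
  invisible(x)
}

# Vectorised continuity-corrected z for a count k of n against p0 = 0.5.
# Returns 0 when |k - n/2| <= 0.5 (the correction would cross the null).
binom_z_stat <- function(k, n) {
  d <- k - n / 2
  ifelse(abs(d) <= 0.5, 0, sign(d) * (abs(d) - 0.5) / sqrt(n / 4))
}

# Vectorised exact two-tailed p for Binomial(n, 0.5): double the smaller
# one-sided tail, cap at 1. By symmetry the smaller tail is P(X <= min(k, n-k)).
binom_exact_p <- function(k, n) {
  pmin(1, 2 * stats::pbinom(pmin(k, n - k), n, 0.5))
}

check_count_pair <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    rlang::abort("`k` and `n` must be single non-missing integers.")
  }
  if (n < 1) rlang::abort("`n` must be at least 1.")
  if (k < 0 || k > n) rlang::abort("`k` must satisfy 0 <= k <= n.")
}

#' Continuity-corrected binomial z test against a fair null
#'
#' Tests whether a count `k` of `n` Bernoulli trials departs from the null
#' proportion 0.5 using the normal approximation with the +/- 0.5 continuity
#' correction. This is the statistic used to report population-level
#' prevalence and direction of eye preference.
#'
#' The statistic is `sign(k - n/2) * (|k - n/2| - 0.5) / sqrt(n/4)`, set to 0
#' when `|k - n/2| <= 0.5`, and the p-value is the two-tailed normal tail
#' probability. It is antisymmetric: `binom_z_test(k, n)` and
#' `binom_z_test(n - k, n)` have opposite-signed statistics.
#'
#' @param k Number of successes (e.g. birds with an eye preference).
#' @param n Number of trials (e.g. analyzable birds).
#' @return A `lat_test` object with fields `statistic` (z), `p_value`,
#'   `method`, `n`, `exact = FALSE`.
#' @seealso [binom_exact_test()] for the exact companion used for per-bird
#'   classification at small n.
#' @examples
#' binom_z_test(54, 74)
#' @export
binom_z_test <- function(k, n) {
  check_count_pair(k, n)
  z <- binom_z_stat(k, n)
  new_lat_test(z, 2 * stats::pnorm(-abs(z)), "binomial_z", n, FALSE,
    k = as.integer(k)
  )
}

#' Exact two-tailed binomial test against a fair null
#'
#' Exact companion to [binom_z_test()]: the two-tailed p-value is obtained by
#' doubling the smaller one-sided tail of Binomial(n, 0.5) and capping at 1
#' (tail-doubling convention, not the minimum-likelihood method). Used by
#' default for per-individual classification, where n (monocular inspections
#' per bird) is small enough that the normal approximation is unreliable.
#'
#' @inheritParams binom_z_test
#' @return A `lat_test` object; `statistic` is the continuity-corrected z
#'   (reported for reference), `p_value` the exact two-tailed p,
#'   `exact = TRUE`.
#' @examples
#' binom_exact_test(14, 15)
#' @export
binom_exact_test <- function(k, n) {
  check_count_pair(k, n)
  new_lat_test(binom_z_stat(k, n), binom_exact_p(k, n), "binomial_exact",
    n, TRUE,
    k = as.integer(k)
  )
}

#' One-sample Wilcoxon signed rank test
#'
#' Tests whether a sample is symmetrically located at `mu`. Differences equal
#' to zero are dropped (classic convention, not Pratt), absolute differences
#' are ranked with average ranks for ties, and the statistic is the signed
#' rank sum `W = sum(sign(d_i) * rank_i)`, so `W > 0` means values tend above
#' `mu`. With at most `exact_max_n` non-zero differences and no ties the
#' p-value is exact (full sign-enumeration distribution); otherwise a normal
#' approximation is used with `Var(W) = sum(rank_i^2)`, which absorbs the tie
#' correction automatically.
#'
#' @param x Numeric values (e.g. per-bird laterality indices, or paired
#'   differences for a matched-pairs test).
#' @param mu Null location, default 0.
#' @param exact_max_n Largest number of non-zero differences for which the
#'   exact distribution is used (ties also force the approximation).
#' @return A `lat_test` object; `n` is the number of non-zero differences.
#' @examples
#' wilcoxon_signed_rank(c(0.4, 0.1, -0.2, 0.6, 0.3))
#' @export
wilcoxon_signed_rank <- function(x, mu = 0, exact_max_n = 20) {
  if (!length(x) || anyNA(x)) {
    rlang::abort("`x` must be non-empty and free of missing values.")
  }
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    rlang::abort("Degenerate input: all values equal `mu` after zero removal.")
  }
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max_n && !ties) {
    w_plus <- sum(r[d > 0])
    p <- min(1, 2 * min(
      stats::psignrank(w_plus, n),
      stats::psignrank(w_plus - 1, n, lower.tail = FALSE)
    ))
    new_lat_test(W, p, "wilcoxon_signed_rank", n, TRUE, n_zero_dropped = length(x) - n)
  } else {
    z <- W / sqrt(sum(r^2))
    new_lat_test(W, 2 * stats::pnorm(-abs(z)), "wilcoxon_signed_rank", n, FALSE,
      n_zero_dropped = length(x) - n
    )
  }
}

# Enumerate the exact two-tailed p of the min-U statistic over all
# choose(N, n_a) group labelings of the pooled ranks.
mwu_exact_p <- function(r_pooled, n_a, u_obs) {
  N <- length(r_pooled)
  n_b <- N - n_a
  idx <- utils::combn(N, n_a)
  Ra <- colSums(matrix(r_pooled[idx], nrow = n_a))
  Ua <- n_a * n_b + n_a * (n_a + 1) / 2 - Ra
  Ub <- n_a * n_b - Ua
  mean(pmin(Ua, Ub) <= u_obs + 1e-9)
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum test of whether two samples come from the same distribution.
#' The reported statistic is `U = min(U_a, U_b)` where
#' `U_a = n_a n_b + n_a(n_a + 1)/2 - R_a` and `R_a` is the rank sum of the
#' first sample over pooled average ranks. When the pooled size is at most
#' `exact_max_total` the two-tailed p-value is exact, computed by enumerating
#' every labeling of the pooled observations; otherwise a normal
#' approximation with tie correction and a 0.5 continuity correction is used.
#' If the pooled values are all identical the test is degenerate and p = 1.
#'
#' @param a,b Numeric samples (e.g. ABS-LI per bird for two food types).
#' @param exact_max_total Largest pooled size for which the enumeration path
#'   is taken.
#' @return A `lat_test` object; `n` is the pooled sample size.
#' @examples
#' mann_whitney_u(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
#' @export
mann_whitney_u <- function(a, b, exact_max_total = 14) {
  if (!length(a) || !length(b)) rlang::abort("Both groups must be non-empty.")
  if (anyNA(a) || anyNA(b)) rlang::abort("Missing values are not allowed.")
  n_a <- length(a)
  n_b <- length(b)
  N <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  Ra <- sum(r[seq_len(n_a)])
  Ua <- n_a * n_b + n_a * (n_a + 1) / 2 - Ra
  Ub <- n_a * n_b - Ua
  U <- min(Ua, Ub)
  if (length(unique(pooled)) == 1L) {
    return(new_lat_test(U, 1, "mann_whitney", N, FALSE, u_a = Ua, u_b = Ub))
  }
  if (N <= exact_max_total) {
    p <- min(1, mwu_exact_p(r, n_a, U))
    new_lat_test(U, p, "mann_whitney", N, TRUE, u_a = Ua, u_b = Ub)
  } else {
    mu <- n_a * n_b / 2
    tt <- table(pooled)
    v <- n_a * n_b / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (v <= 0) {
      return(new_lat_test(U, 1, "mann_whitney", N, FALSE, u_a = Ua, u_b = Ub))
    }
    z <- (U - mu + 0.5) / sqrt(v) # U <= mu by construction
    p <- min(1, 2 * stats::pnorm(z))
    new_lat_test(U, p, "mann_whitney", N, FALSE, u_a = Ua, u_b = Ub)
  }
}

#' Kruskal-Wallis rank test across several groups
#'
#' Omnibus test that k independent samples share one distribution, with the
#' standard tie correction:
#' `H = [12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1)] / (1 - sum(t^3 - t)/(N^3 - N))`
#' over average ranks, referred to a chi-square distribution with k - 1
#' degrees of freedom. H is invariant under any strictly increasing
#' transformation of the pooled values.
#'
#' @param x Either a list of numeric vectors (one per group) or a numeric
#'   vector accompanied by `g`.
#' @param g Group labels, required when `x` is a vector.
#' @return A `lat_test` object with `statistic` H, `df` and `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  groups <- if (is.list(x)) {
    x
  } else {
    if (is.null(g)) rlang::abort("Provide `g` when `x` is not a list.")
    unname(split(x, g))
  }
  if (length(groups) < 2L) rlang::abort("Need at least two groups.")
  if (any(!lengths(groups))) rlang::abort("Every group must be non-empty.")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) rlang::abort("Missing values are not allowed.")
  if (length(unique(pooled)) == 1L) {
    rlang::abort("Degenerate input: all pooled values are identical.")
  }
  N <- length(pooled)
  r <- rank(pooled)
  gi <- rep(seq_along(groups), lengths(groups))
  Rj <- vapply(split(r, gi), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / lengths(groups)) - 3 * (N + 1)
  tt <- table(pooled)
  H <- H / (1 - sum(tt^3 - tt) / (N^3 - N))
  df <- length(groups) - 1L
  new_lat_test(H, stats::pchisq(H, df, lower.tail = FALSE), "kruskal_wallis",
    N, FALSE,
    df = df
  )
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two raters assigning the same items to
#' the same categories, from the square confusion matrix of category counts
#' (rater 1 in rows, rater 2 in columns). Reports kappa, its large-sample
#' standard error (Fleiss-Cohen-Everitt), and the raw percent agreement.
#' The p-value refers to the normal test of kappa = 0.
#'
#' @param confusion Square numeric matrix of non-negative counts.
#' @return A `lat_test` object with `statistic` kappa, plus `se`,
#'   `percent_agreement`, `po` and `pe` components.
#' @examples
#' m <- diag(c(20, 15, 15))
#' cohens_kappa(m) # perfect agreement
#' @export
cohens_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) rlang::abort("`confusion` must be square.")
  if (any(m < 0) || anyNA(m)) rlang::abort("Counts must be non-negative.")
  N <- sum(m)
  if (N < 1) rlang::abort("Total count must be at least 1.")
  p <- m / N
  po <- sum(diag(p))
  rowm <- rowSums(p)
  colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12) {
    rlang::abort("Degenerate margins: expected agreement is 1.")
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  k_idx <- seq_len(nrow(m))
  A <- sum(diag(p) * (1 - (rowm + colm) * (1 - kappa))^2)
  B <- 0
  for (i in k_idx) {
    for (j in k_idx) {
      if (i != j) B <- B + p[i, j] * (colm[i] + rowm[j])^2
    }
  }
  B <- (1 - kappa)^2 * B
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, (A + B - C) / (N * (1 - pe)^2)))
  p_val <- if (se > 0) 2 * stats::pnorm(-abs(kappa) / se) else as.numeric(kappa != 1)
  new_lat_test(kappa, min(1, p_val), "kappa", N, FALSE,
    se = se, percent_agreement = 100 * po, po = po, pe = pe
  )
}
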