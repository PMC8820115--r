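# Brute-force enumeration oracles, kept independent of the implementation
# paths they check (direct pmf summation, sign enumeration, labeling
# enumeration with pairwise comparison counts).

oracle_binom_exact_p <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

oracle_signed_rank <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  w_all <- signs %*% r
  list(W = w_obs, p = mean(abs(w_all) >= abs(w_obs) - 1e-9))
}

# U by direct pairwise comparison; exact p by enumerating every labeling of
# the pooled sample.
oracle_mwu <- function(a, b) {
  u_pair <- function(x, y) sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- min(u_pair(a, b), u_pair(b, a))
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_all <- apply(idx, 2, function(i) {
    min(u_pair(pooled[i], pooled[-i]), u_pair(pooled[-i], pooled[i]))
  })
  list(U = u_obs, p = mean(u_all <= u_obs + 1e-9))
}

# Random tie-free sample (distinct values) of size n.
rand_distinct <- function(n, spread = 100) sample(seq_len(spread), n)

# Per-bird error-event table for the balanced design: each bird contributes
# `n_errors` errors whose inspecting eye is drawn with P(non-preferred eye)
# = p_nonpref; all birds LEFT-preferring (label symmetry is tested
# separately).
make_error_events <- function(n_birds, p_nonpref = 0.5, n_errors = 6,
                              preference = "LEFT") {
  nonpref_eye <- if (preference == "LEFT") "R" else "L"
  pref_eye <- if (preference == "LEFT") "L" else "R"
  tibble::tibble(
    bird_id = rep(sprintf("b%04d", seq_len(n_birds)), each = n_errors),
    preference = preference,
    inspection_eye = ifelse(
      stats::runif(n_birds * n_errors) < p_nonpref, nonpref_eye, pref_eye
    ),
    t_peck_s = rep(seq_len(n_errors), n_birds)
  )
}

# Classified-bird table built from group counts, with per-bird inspection
# splits chosen to land in the requested class at alpha = 0.05, n = 20.
make_classified <- function(n_left, n_right, n_none, food_type = "all") {
  counts <- list(
    LEFT = c(18L, 2L), RIGHT = c(2L, 18L), NONE = c(10L, 10L)
  )
  cls <- rep(c("LEFT", "RIGHT", "NONE"), c(n_left, n_right, n_none))
  birds <- tibble::tibble(
    bird_id = sprintf("b%04d", seq_along(cls)),
    food_type = food_type,
    n_left = unname(vapply(cls, function(c) counts[[c]][1], integer(1))),
    n_right = unname(vapply(cls, function(c) counts[[c]][2], integer(1)))
  )
  classify_birds(birds)
}
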