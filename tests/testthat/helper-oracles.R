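# Independent oracles and shared fixtures. The oracles deliberately use
# naive O(n1*n0) enumeration so they share no code path with the package's
# rank-based implementations.

# Mann-Whitney AUC by explicit pair enumeration (ties count 1/2).
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# DeLong variance from structural components built by double loop.
oracle_delong_variance <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(pos, function(a) mean(vapply(neg, function(b) psi(a, b),
                                             numeric(1))), numeric(1))
  v01 <- vapply(neg, function(b) mean(vapply(pos, function(a) psi(a, b),
                                             numeric(1))), numeric(1))
  var(v10) / length(pos) + var(v01) / length(neg)
}

# Random small prediction instance; with prob. tie_prob scores are drawn
# from a small discrete support to force ties.
random_instance <- function(n_max = 50, tie_prob = 0.5) {
  n1 <- sample(2:(n_max / 2), 1)
  n0 <- sample(2:(n_max / 2), 1)
  y <- c(rep(1L, n1), rep(0L, n0))
  s <- if (runif(1) < tie_prob) {
    sample(seq(0, 1, by = 0.25), n1 + n0, replace = TRUE)
  } else {
    runif(n1 + n0)
  }
  list(y = y, s = s)
}

# Small calibrated-free cohort for regimen/experiment tests.
small_cohort <- function(n = 120, prevalence = 0.5, seed = 1,
                         effect_scale = 1.5) {
  spec <- cohort_spec(n, prevalence, n_continuous = 4, n_binary = 2,
                      effect_scale = effect_scale, seed = seed)
  generate_cohort(spec)
}

# Fit-free scorer keyed to the first feature (monotone in the signal).
monotone_scorer <- function() fixed_scorer(function(x) plogis(x[, 1]))
constant_scorer <- function() fixed_scorer(function(x) rep(0.5, nrow(x)))
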