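# Monte Carlo verification layer. Every analytic quantity in the package
# (decision rates, the significance mixture, confidence-bound coverage) has
# a seeded simulator here so it can be checked empirically.
#
# RNG contract: one set.seed(seed) per simulation run; draws are laid out
# animals-within-replicate (column-major), replicates outer, so a given
# seed yields a bit-reproducible stream.

#' Simulate the majority rule
#'
#' Draws `m` subject outcomes per replicate from an outcome distribution,
#' classifies each replicate with [classify_sample()], and returns
#' empirical correct/incorrect/inconclusive rates. For large `n_reps` each
#' rate lies within a few binomial standard errors of the analytic
#' [rule_rates()].
#'
#' @inheritParams rule_rates
#' @param n_reps Number of replicates.
#' @param seed Integer seed for the random number generator.
#' @return A `"decision_rates"` object with `empirical = TRUE`.
#' @examples
#' simulate_rule(c(0.9, 0.1), 3, n_reps = 10000, seed = 1)
#' @export
simulate_rule <- function(probs, m, n_reps, seed) {
  probs <- check_outcome_dist(probs)
  m <- check_count(m, "m", min = 1L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  set.seed(seed)
  k <- length(probs)
  t <- majority_threshold(m)
  outcomes <- matrix(sample.int(k, m * n_reps, replace = TRUE, prob = probs),
                     nrow = m)
  correct <- mean(colSums(outcomes == 1L) >= t)
  incorrect <- 0
  if (k > 1L) {
    for (j in 2:k) incorrect <- incorrect + mean(colSums(outcomes == j) >= t)
  }
  new_decision_rates(correct, incorrect, 1 - correct - incorrect, m,
                     empirical = TRUE, n_reps = n_reps)
}

#' Simulate per-subject significance tests
#'
#' Per replicate, each of `m` subjects carries the outcome with probability
#' `gamma`; a carrier's test is significant with probability `beta`, a
#' non-carrier's with probability `alpha`. Returns the empirical
#' distribution of N, the number of significant subjects per replicate,
#' whose mean rate N/m converges to `p_from_gamma(gamma, alpha, beta)`.
#'
#' @inheritParams gamma_lower_bound
#' @inheritParams simulate_rule
#' @param gamma True typicality of the outcome in the population.
#' @return A list with `counts` (named vector: replicates with N = 0..m
#'   significant subjects), `mean_rate` (empirical significance rate) and
#'   `p_expected` (the analytic mixture probability).
#' @examples
#' simulate_significance(0.5, m = 1, n_reps = 10000, seed = 1)$mean_rate
#' @export
simulate_significance <- function(gamma, alpha = 0.05, beta = 1, m, n_reps,
                                  seed) {
  gamma <- check_prob(gamma, "gamma")
  tc <- check_characteristics(alpha, beta)
  m <- check_count(m, "m", min = 1L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  set.seed(seed)
  n_sig <- draw_significant_counts(gamma, tc, m, n_reps)
  counts <- tabulate(n_sig + 1L, nbins = m + 1L)
  names(counts) <- 0:m
  list(counts = counts, mean_rate = mean(n_sig) / m,
       p_expected = p_from_gamma(gamma, tc$alpha, tc$beta))
}

# m x n_reps column-major draws: carrier status then test outcome per animal.
draw_significant_counts <- function(gamma, tc, m, n_reps) {
  carrier <- matrix(stats::runif(m * n_reps) < gamma, nrow = m)
  p_sig <- ifelse(carrier, tc$beta, tc$alpha)
  significant <- matrix(stats::runif(m * n_reps), nrow = m) < p_sig
  colSums(significant)
}

#' Empirical coverage of the typicality lower bound
#'
#' Simulates samples at a known typicality `gamma` (as in
#' [simulate_significance()]), computes the lower confidence bound
#' [gamma_lower_bound()] for each replicate's tally, and returns the
#' fraction of replicates whose bound does not exceed the true `gamma`.
#' Exact equal-tailed intervals are conservative, so the coverage is at
#' least the nominal level up to Monte Carlo error.
#'
#' @inheritParams simulate_significance
#' @inheritParams gamma_lower_bound
#' @return The empirical coverage as a single probability.
#' @examples
#' coverage_check(0.7, m = 5, sided = "one.sided", n_reps = 5000, seed = 1)
#' @export
coverage_check <- function(gamma, alpha = 0.05, beta = 1, m, level = 0.95,
                           sided = c("two.sided", "one.sided"), n_reps, seed) {
  gamma <- check_prob(gamma, "gamma")
  tc <- check_characteristics(alpha, beta)
  m <- check_count(m, "m", min = 1L)
  sided <- check_sided(sided)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  set.seed(seed)
  n_sig <- draw_significant_counts(gamma, tc, m, n_reps)
  # gamma_c only depends on the tally, so precompute for N = 0..m
  bounds <- vapply(0:m, function(n) {
    p_lower <- lower_bound_p(n, m, level, sided)
    min(1, max(0, (p_lower - tc$alpha) / (tc$beta - tc$alpha)))
  }, numeric(1))
  mean(bounds[n_sig + 1L] <= gamma)
}
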