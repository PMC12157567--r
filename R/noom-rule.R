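# N-out-of-M majority decision rule: analytic correct / incorrect /
# inconclusive rates for an arbitrary outcome distribution, a brute-force
# enumeration oracle, and threshold solving on the single-outlier error curve.

# First element of `probs` is the representative (modal) outcome; the rest
# are outlier types. Must sum to 1 and have a strict maximum at the front.
check_outcome_dist <- function(probs) {
  if (!is.numeric(probs) || length(probs) < 1L || anyNA(probs)) {
    stop("`probs` must be a numeric vector of outcome probabilities",
         call. = FALSE)
  }
  if (any(probs < 0)) {
    stop("outcome probabilities must be non-negative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop(sprintf("outcome probabilities must sum to 1 (got %.15g)", sum(probs)),
         call. = FALSE)
  }
  if (length(probs) > 1L && probs[1] <= max(probs[-1])) {
    stop("the first outcome (the representative) must be the strict maximum",
         call. = FALSE)
  }
  as.numeric(probs)
}

#' Strict majority threshold
#'
#' Smallest count that constitutes a strict majority of `m` subjects:
#' `floor(m/2) + 1`. With this threshold at most one outcome can reach a
#' majority, so correct/incorrect/inconclusive classifications are mutually
#' exclusive for every `m`.
#'
#' @param m Number of tested subjects (>= 1).
#' @return The majority threshold as an integer.
#' @examples
#' majority_threshold(3) # 2
#' @export
majority_threshold <- function(m) {
  m <- check_count(m, "m", min = 1L)
  m %/% 2L + 1L
}

#' Classify one sample under the majority rule
#'
#' Given per-outcome counts for one sample of `m` subjects (aligned with an
#' outcome distribution whose first label is the representative), returns
#' `"correct"` if the representative reaches a strict majority,
#' `"incorrect"` if any outlier does, and `"inconclusive"` otherwise.
#'
#' @param counts Integer vector of per-outcome counts, summing to `m`.
#' @param m Number of tested subjects.
#' @return One of `"correct"`, `"incorrect"`, `"inconclusive"`.
#' @examples
#' classify_sample(c(1, 1, 1), 3) # inconclusive
#' @export
classify_sample <- function(counts, m) {
  m <- check_count(m, "m", min = 1L)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) != m) {
    stop(sprintf("`counts` must sum to m = %d (got %d)", m, sum(counts)),
         call. = FALSE)
  }
  t <- majority_threshold(m)
  if (counts[1] >= t) return("correct")
  if (length(counts) > 1L && any(counts[-1] >= t)) return("incorrect")
  "inconclusive"
}

new_decision_rates <- function(correct, incorrect, inconclusive, m,
                               empirical = FALSE, n_reps = NULL) {
  structure(
    list(correct = correct, incorrect = incorrect, inconclusive = inconclusive,
         m = m, threshold = majority_threshold(m), empirical = empirical,
         n_reps = n_reps),
    class = "decision_rates")
}

#' @export
print.decision_rates <- function(x, ...) {
  cat(sprintf("%s decision rates of the %d-oo-%d majority rule%s\n",
              if (x$empirical) "Empirical" else "Analytic",
              x$threshold, x$m,
              if (x$empirical) sprintf(" (%d replicates)", x$n_reps) else ""))
  cat(sprintf("  correct (pi):       %.4f\n", x$correct))
  cat(sprintf("  incorrect (delta):  %.4f\n", x$incorrect))
  cat(sprintf("  inconclusive:       %.4f\n", x$inconclusive))
  invisible(x)
}

#' Analytic rates of the N-out-of-M majority rule
#'
#' Probability that a sample of `m` subjects drawn from an outcome
#' distribution yields a correct conclusion (the representative outcome
#' reaches a strict majority, probability pi), an incorrect conclusion
#' (some outlier type reaches a majority, probability delta), or is
#' inconclusive (no outcome reaches a majority). Majority events are
#' disjoint, so each rate is a binomial upper-tail probability:
#' `P(X_j >= threshold)` with `X_j ~ Binomial(m, probs[j])`.
#'
#' @param probs Outcome distribution; the first element is the
#'   representative outcome's probability and must be the strict maximum.
#' @param m Number of tested subjects.
#' @return A `"decision_rates"` object with elements `correct`,
#'   `incorrect` and `inconclusive` (summing to 1).
#' @examples
#' rule_rates(c(0.9, 0.1), 3)               # delta = 0.028
#' rule_rates(c(0.8, 0.1, 0.05, 0.05), 3)   # delta = 0.0425
#' @export
rule_rates <- function(probs, m) {
  probs <- check_outcome_dist(probs)
  m <- check_count(m, "m", min = 1L)
  t <- majority_threshold(m)
  tails <- stats::pbinom(t - 1, m, probs, lower.tail = FALSE)
  correct <- tails[1]
  incorrect <- sum(tails[-1])
  new_decision_rates(correct, incorrect, 1 - correct - incorrect, m)
}

#' Error rate of the majority rule with a single outlier type
#'
#' delta as a function of the total outlier probability omega when all
#' outliers are of one type, i.e. the outcome distribution is
#' `(1 - omega, omega)`. For the 2-oo-3 rule this is
#' `3 omega^2 (1 - omega) + omega^3`; for 1-oo-1 it is omega itself.
#' omega must stay below 0.5 so the representative remains the modal
#' outcome.
#'
#' @param m Number of tested subjects.
#' @param omega Numeric vector of outlier probabilities in \[0, 0.5).
#' @return delta evaluated at each grid point.
#' @examples
#' delta_curve(3, c(0.1, 0.2)) # 0.028, 0.104
#' @export
delta_curve <- function(m, omega) {
  m <- check_count(m, "m", min = 1L)
  if (!is.numeric(omega) || anyNA(omega) || any(omega < 0 | omega >= 0.5)) {
    stop("`omega` must lie in [0, 0.5) so the representative stays modal",
         call. = FALSE)
  }
  t <- majority_threshold(m)
  stats::pbinom(t - 1, m, omega, lower.tail = FALSE)
}

#' Error-rate reduction of 2-oo-3 relative to 1-oo-1
#'
#' The difference `delta(1-oo-1) - delta(2-oo-3) = omega - (3 omega^2 -
#' 2 omega^3)` for a single outlier type. Non-negative on \[0, 0.5) and
#' maximal near omega = 0.211, so moving from one to three subjects helps
#' most for intermediate outlier probabilities and little at either extreme.
#'
#' @param omega Numeric vector of outlier probabilities in \[0, 0.5).
#' @return The delta difference at each grid point.
#' @examples
#' delta_difference(0.1) # 0.072
#' @export
delta_difference <- function(omega) {
  delta_curve(1, omega) - delta_curve(3, omega)
}

#' Outlier probability at which the majority rule reaches a target error
#'
#' Solves `delta(omega) = delta_target` for the single-outlier-type curve of
#' [delta_curve()] by bisection on (0, 0.5) to an omega tolerance of 1e-10.
#' The companion typicality threshold is `1 - omega`: the rule keeps
#' `delta <= delta_target` only when the representative's typicality is at
#' least that high.
#'
#' @param m Number of tested subjects.
#' @param delta_target Target error rate, strictly between 0 and the value
#'   of the delta curve at omega = 0.5.
#' @return The unique omega in (0, 0.5) with `delta(omega) = delta_target`.
#' @examples
#' omega_threshold(3, 0.05) # about 0.1354
#' @export
omega_threshold <- function(m, delta_target) {
  m <- check_count(m, "m", min = 1L)
  t <- majority_threshold(m)
  delta_max <- stats::pbinom(t - 1, m, 0.5, lower.tail = FALSE)
  delta_target <- check_prob(delta_target, "delta_target",
                             lower = 0, upper = delta_max,
                             lower_open = TRUE, upper_open = TRUE)
  f <- function(w) stats::pbinom(t - 1, m, w, lower.tail = FALSE) - delta_target
  lo <- 0
  hi <- 0.5
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Minimal typicality keeping the majority rule below a target error rate
#'
#' Scans integer-percent outlier probabilities, finds the largest omega (in
#' whole percent) whose single-outlier delta does not exceed
#' `delta_target`, and returns the companion typicality `100 - omega` in
#' percent. With the defaults (2-oo-3, 5% target) this is 87: the rule only
#' keeps its error rate acceptable when the representative outcome's
#' typicality is at least 87%.
#'
#' @inheritParams omega_threshold
#' @return The minimal typicality as an integer percent.
#' @examples
#' typicality_threshold() # 87
#' @export
typicality_threshold <- function(m = 3, delta_target = 0.05) {
  m <- check_count(m, "m", min = 1L)
  omega_pc <- 0:49
  delta <- delta_curve(m, omega_pc / 100)
  100L - max(omega_pc[delta <= delta_target])
}

#' Brute-force enumeration oracle for the majority-rule rates
#'
#' Enumerates all `K^m` ordered outcome assignments (K outcome types),
#' classifies each with [classify_sample()], and accumulates multinomial
#' probabilities. Mathematically identical to [rule_rates()]; kept as an
#' independent check of the disjoint-tail argument. Guarded at
#' `K^m <= 1e7`.
#'
#' @inheritParams rule_rates
#' @return A `"decision_rates"` object.
#' @examples
#' enumerate_exact(c(0.8, 0.15, 0.05), 3) # delta = 0.068
#' @export
enumerate_exact <- function(probs, m) {
  probs <- check_outcome_dist(probs)
  m <- check_count(m, "m", min = 1L)
  k <- length(probs)
  if (k^m > 1e7) {
    stop(sprintf("enumeration of %d^%d assignments exceeds the 1e7 guard",
                 k, m), call. = FALSE)
  }
  assign_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m),
                                       KEEP.OUT.ATTRS = FALSE))
  rates <- c(correct = 0, incorrect = 0, inconclusive = 0)
  for (r in seq_len(nrow(assign_grid))) {
    labels <- assign_grid[r, ]
    counts <- tabulate(labels, nbins = k)
    cls <- classify_sample(counts, m)
    rates[cls] <- rates[cls] + prod(probs[labels])
  }
  new_decision_rates(rates[["correct"]], rates[["incorrect"]],
                     rates[["inconclusive"]], m)
}
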