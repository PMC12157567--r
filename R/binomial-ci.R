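#' Binomial probability mass function
#'
#' Probability of observing exactly `i` subjects with the outcome among `m`
#' independently tested subjects when each shows it with probability `p`.
#'
#' @param i Number of subjects showing the outcome (0 <= i <= m).
#' @param m Number of subjects tested.
#' @param p Per-subject probability of the outcome.
#' @return The probability choose(m, i) * p^i * (1 - p)^(m - i).
#' @examples
#' binomial_pmf(3, 3, 0.525) # 0.525^3
#' @export
binomial_pmf <- function(i, m, p) {
  tl <- check_tally(i, m)
  p <- check_prob(p, "p")
  stats::dbinom(tl$n, tl$m, p)
}

ci_tail_mass <- function(level, sided) {
  if (sided == "two.sided") (1 - level) / 2 else 1 - level
}

#' Exact lower confidence bound for a binomial proportion
#'
#' Equal-tailed (Clopper-Pearson) lower bound for the per-subject success
#' probability `p` given `n` successes in `m` trials: the value of p at which
#' the upper-tail probability P(X >= n) equals the allotted tail mass
#' ((1 - level)/2 for a two-sided interval, 1 - level for a one-sided
#' lower bound). By the standard exact-interval convention the bound is 0
#' when `n = 0`.
#'
#' @param n Number of successes observed.
#' @param m Number of trials.
#' @param level Confidence level, e.g. 0.95.
#' @param sided `"two.sided"` for an equal-tailed interval or `"one.sided"`
#'   for a lower confidence bound only.
#' @return The exact lower confidence bound for p.
#' @seealso [upper_bound_p()], [gamma_lower_bound()]
#' @examples
#' lower_bound_p(2, 2, 0.95, "one.sided") # sqrt(0.05)
#' @export
lower_bound_p <- function(n, m, level = 0.95, sided = c("two.sided", "one.sided")) {
  tl <- check_tally(n, m)
  level <- check_prob(level, "level", lower_open = TRUE, upper_open = TRUE)
  sided <- check_sided(sided)
  if (tl$n == 0L) return(0)
  stats::qbeta(ci_tail_mass(level, sided), tl$n, tl$m - tl$n + 1)
}

#' Exact upper confidence bound for a binomial proportion
#'
#' Equal-tailed (Clopper-Pearson) upper bound: the value of p at which the
#' lower-tail probability P(X <= n) equals (1 - level)/2. The bound is 1
#' when `n = m`. One-sided intervals in this package are lower-only, so
#' requesting the upper bound of a one-sided interval is an error.
#'
#' @inheritParams lower_bound_p
#' @return The exact upper confidence bound for p.
#' @examples
#' upper_bound_p(0, 2) # 1 - sqrt(0.025)
#' @export
upper_bound_p <- function(n, m, level = 0.95, sided = c("two.sided", "one.sided")) {
  tl <- check_tally(n, m)
  level <- check_prob(level, "level", lower_open = TRUE, upper_open = TRUE)
  sided <- check_sided(sided)
  if (sided == "one.sided") {
    stop("one-sided intervals are lower-only; no upper bound is defined",
         call. = FALSE)
  }
  if (tl$n == tl$m) return(1)
  stats::qbeta(1 - ci_tail_mass(level, sided), tl$n + 1, tl$m - tl$n)
}

#' Exact confidence interval for a binomial proportion
#'
#' Convenience wrapper bundling [lower_bound_p()] and [upper_bound_p()].
#' For a one-sided interval the upper limit is 1 by convention.
#'
#' @inheritParams lower_bound_p
#' @return A list with elements `lower`, `upper`, `level` and `sided`.
#' @export
proportion_interval <- function(n, m, level = 0.95,
                                sided = c("two.sided", "one.sided")) {
  sided <- check_sided(sided)
  lower <- lower_bound_p(n, m, level, sided)
  upper <- if (sided == "one.sided") 1 else upper_bound_p(n, m, level, sided)
  list(lower = lower, upper = upper, level = level, sided = sided)
}
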