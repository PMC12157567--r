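# One-sided binomial-tail tests of null hypotheses about typicality:
# majority-null (gamma0 = 0.5), global-null (gamma0 = 0), or any gamma0.

#' One-sided p-value for a hypothesized typicality
#'
#' Tests the null hypothesis that the typicality equals `gamma0` against
#' larger values. Under the null each of the `m` subjects is significant
#' with probability `p0 = alpha + (beta - alpha) * gamma0`
#' ([p_from_gamma()]); the p-value is the upper-tail probability
#' `P(X >= n | m, p0)`.
#'
#' `gamma0 = 0.5` is the majority-null hypothesis (the outcome is present
#' in less than half the population); `gamma0 = 0` is the global-null
#' hypothesis (the outcome is absent from every member), for which the
#' 1-oo-1 p-value equals the per-subject false-positive rate `alpha`.
#'
#' Note the tail convention: the p-value counts samples with `n` *or more*
#' significant subjects, which is the convention that reproduces the
#' published reference values (e.g. 0.525 for 1-oo-1 under the
#' majority-null).
#'
#' @inheritParams gamma_lower_bound
#' @param gamma0 Hypothesized typicality, in \[0, 1\].
#' @return The one-sided p-value (1 when `n = 0`).
#' @examples
#' typicality_pvalue(5, 5, gamma0 = 0.5) # 0.525^5
#' typicality_pvalue(1, 1, gamma0 = 0)   # 0.05
#' @export
typicality_pvalue <- function(n, m, gamma0 = 0.5, alpha = 0.05, beta = 1) {
  tl <- check_tally(n, m)
  gamma0 <- check_prob(gamma0, "gamma0")
  p0 <- p_from_gamma(gamma0, alpha, beta)
  if (tl$n == 0L) return(1)
  stats::pbinom(tl$n - 1L, tl$m, p0, lower.tail = FALSE)
}

#' Table of typicality p-values for all (N, M) up to m_max
#'
#' @inheritParams typicality_pvalue
#' @param m_max Largest number of tested subjects to tabulate.
#' @return A lower-triangular numeric matrix with rows `M = 1..m_max` and
#'   columns `N = 0..m_max` of unrounded one-sided p-values; `NA` above the
#'   diagonal. The `N = M` diagonal equals `p0^M` exactly (0.525^M for the
#'   majority-null, 0.05^M for the global-null at the defaults).
#' @examples
#' round(pvalue_table(3, gamma0 = 0), 4)
#' @export
pvalue_table <- function(m_max = 10, gamma0 = 0.5, alpha = 0.05, beta = 1) {
  m_max <- check_count(m_max, "m_max", min = 1L)
  out <- matrix(NA_real_, nrow = m_max, ncol = m_max + 1,
                dimnames = list(M = 1:m_max, N = 0:m_max))
  for (m in 1:m_max) {
    for (n in 0:m) {
      out[m, n + 1] <- typicality_pvalue(n, m, gamma0, alpha, beta)
    }
  }
  out
}

#' Emission rounding for p-values
#'
#' Rounds half-up to 4 decimal places, switching to 3 significant digits
#' (also half-up, so e.g. 3.125e-7 prints as 3.13e-07) for values below
#' 1e-4. This is the convention used for the published reference tables.
#'
#' @param p Numeric vector of p-values.
#' @return The rounded numeric vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p) | p >= 1e-4, round_half_up(p, 4), signif_half_up(p, 3))
}
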