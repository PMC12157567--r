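#' Per-subject significance probability implied by a typicality
#'
#' A subject drawn from the population carries the outcome with probability
#' `gamma` (the typicality, also called prevalence). An imperfect per-subject
#' test then comes out significant with probability `beta` (sensitivity) if
#' the outcome is carried and `alpha` (false-positive rate) if not, so the
#' overall significance probability is the mixture
#' `p = gamma * beta + (1 - gamma) * alpha = alpha + (beta - alpha) * gamma`.
#'
#' @param gamma Typicality of the outcome in the population, in \[0, 1\].
#' @param alpha Per-subject false-positive rate (default 0.05).
#' @param beta Per-subject sensitivity (default 1; see Details in
#'   [gamma_lower_bound()] for why 1 is the conservative choice).
#' @return The per-subject significance probability, in \[alpha, beta\].
#' @examples
#' p_from_gamma(0.5) # 0.525 with the default alpha = 0.05, beta = 1
#' @export
p_from_gamma <- function(gamma, alpha = 0.05, beta = 1) {
  tc <- check_characteristics(alpha, beta)
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma < 0 | gamma > 1)) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  tc$alpha + (tc$beta - tc$alpha) * gamma
}

#' Typicality implied by a per-subject significance probability
#'
#' Inverts the mixture of [p_from_gamma()]: `gamma = (p - alpha) / (beta -
#' alpha)`. The raw value is negative when `p < alpha` and exceeds 1 when
#' `p > beta` (possible whenever `beta < 1`); with `clip = TRUE` (the
#' default) the result is clipped to \[0, 1\].
#'
#' @param p Per-subject significance probability, in \[0, 1\].
#' @param clip Clip the result to \[0, 1\]?
#' @inheritParams p_from_gamma
#' @return The implied typicality (clipped to \[0, 1\] unless `clip = FALSE`).
#' @examples
#' gamma_from_p(0.22361) # about 0.183
#' gamma_from_p(0.03, clip = FALSE) # negative raw value
#' @export
gamma_from_p <- function(p, alpha = 0.05, beta = 1, clip = TRUE) {
  tc <- check_characteristics(alpha, beta)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  g <- (p - tc$alpha) / (tc$beta - tc$alpha)
  if (clip) g <- pmin(1, pmax(0, g))
  g
}

#' Lower confidence bound on typicality
#'
#' The conjunction-analysis lower bound gamma_c: the exact lower confidence
#' bound on the per-subject significance rate p (from `n` significant
#' subjects out of `m` tested; see [lower_bound_p()]) transformed to the
#' typicality scale with [gamma_from_p()] and clipped to \[0, 1\].
#'
#' @details
#' The sensitivity `beta` cannot be estimated from the sample: a
#' non-significant test under `beta < 1` may be a false negative, and
#' lowering `beta` inflates the bound without limit. The conservative
#' assumption is therefore `beta = 1` (the default); a `beta < 1` is
#' accepted for sensitivity exploration but triggers a warning.
#'
#' @inheritParams lower_bound_p
#' @inheritParams p_from_gamma
#' @return An object of class `"typicality_bound"`: a list with elements
#'   `gamma_c` (clipped lower bound), `gamma_raw` (unclipped), `clipped`
#'   (logical), `p_lower` (the bound on p), and the inputs `n`, `m`,
#'   `alpha`, `beta`, `level`, `sided`.
#' @examples
#' gamma_lower_bound(2, 3, sided = "one.sided") # gamma_c about 0.09
#' @export
gamma_lower_bound <- function(n, m, alpha = 0.05, beta = 1, level = 0.95,
                              sided = c("two.sided", "one.sided")) {
  tc <- check_characteristics(alpha, beta)
  sided <- check_sided(sided)
  if (tc$beta < 1) {
    warning("beta < 1 inflates the typicality bound; beta = 1 is the ",
            "conservative assumption", call. = FALSE)
  }
  p_lower <- lower_bound_p(n, m, level, sided)
  raw <- (p_lower - tc$alpha) / (tc$beta - tc$alpha)
  gamma_c <- min(1, max(0, raw))
  structure(
    list(gamma_c = gamma_c, gamma_raw = raw, clipped = !identical(raw, gamma_c),
         p_lower = p_lower, n = n, m = m, alpha = tc$alpha, beta = tc$beta,
         level = level, sided = sided),
    class = "typicality_bound")
}

#' @export
print.typicality_bound <- function(x, ...) {
  cat(sprintf(
    "Lower bound on typicality (%s %g%% interval)\n",
    sub("\\.", "-", x$sided), 100 * x$level))
  cat(sprintf("  %d of %d subjects significant; alpha = %g, beta = %g\n",
              x$n, x$m, x$alpha, x$beta))
  cat(sprintf("  p lower bound: %.5f\n", x$p_lower))
  cat(sprintf("  gamma_c: %.1f%%%s\n", 100 * x$gamma_c,
              if (x$clipped) sprintf(" (raw %.1f%% clipped)", 100 * x$gamma_raw)
              else ""))
  invisible(x)
}

#' Table of typicality lower bounds for all (N, M) up to m_max
#'
#' @inheritParams gamma_lower_bound
#' @param m_max Largest number of tested subjects to tabulate.
#' @param percent Return values on the percent scale (default) rather than
#'   as proportions. Values are unrounded; emission rounding lives in
#'   [run_report()].
#' @return A lower-triangular numeric matrix with rows `M = 1..m_max`,
#'   columns `N = 0..m_max`, and `NA` above the diagonal.
#' @examples
#' gt <- gamma_table(3)
#' round(gt, 1)
#' @export
gamma_table <- function(m_max = 10, alpha = 0.05, beta = 1, level = 0.95,
                        sided = c("two.sided", "one.sided"), percent = TRUE) {
  m_max <- check_count(m_max, "m_max", min = 1L)
  tc <- check_characteristics(alpha, beta)
  sided <- check_sided(sided)
  out <- matrix(NA_real_, nrow = m_max, ncol = m_max + 1,
                dimnames = list(M = 1:m_max, N = 0:m_max))
  for (m in 1:m_max) {
    for (n in 0:m) {
      p_lower <- lower_bound_p(n, m, level, sided)
      out[m, n + 1] <- min(1, max(0, (p_lower - tc$alpha) / (tc$beta - tc$alpha)))
    }
  }
  if (percent) out * 100 else out
}

#' Sensitivity of the typicality bound to the test characteristics
#'
#' Recomputes gamma_c for a fixed sample tally over grids of the per-subject
#' false-positive rate `alpha` and sensitivity `beta` (recycled to a common
#' length; every pair must satisfy `alpha < beta`). gamma_c decreases as
#' `alpha` grows at fixed `beta`, and grows as `beta` is lowered at fixed
#' `alpha` — which is why `beta = 1` is the conservative choice.
#'
#' @inheritParams gamma_lower_bound
#' @param alpha,beta Numeric vectors of test characteristics.
#' @return A data frame with columns `alpha`, `beta`, `gamma_raw` and
#'   `gamma_c` (clipped, as a proportion).
#' @examples
#' gamma_sensitivity(2, 3, alpha = c(0.05, 0.01, 0.001), beta = 1,
#'                   sided = "one.sided")
#' @export
gamma_sensitivity <- function(n, m, alpha, beta, level = 0.95,
                              sided = c("two.sided", "one.sided")) {
  sided <- check_sided(sided)
  k <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, k)
  beta <- rep_len(beta, k)
  for (i in seq_len(k)) check_characteristics(alpha[i], beta[i])
  p_lower <- lower_bound_p(n, m, level, sided)
  raw <- (p_lower - alpha) / (beta - alpha)
  data.frame(alpha = alpha, beta = beta, gamma_raw = raw,
             gamma_c = pmin(1, pmax(0, raw)))
}
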