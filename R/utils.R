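# Internal argument checks and numeric helpers shared across modules.

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 name, min, deparse(substitute(x))), call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, lower = 0, upper = 1,
                       lower_open = FALSE, upper_open = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("`%s` must be a single probability", name), call. = FALSE)
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` must lie in %s%g, %g%s (got %g)", name,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]", x), call. = FALSE)
  }
  as.numeric(x)
}

check_tally <- function(n, m) {
  m <- check_count(m, "m", min = 1L)
  n <- check_count(n, "n", min = 0L)
  if (n > m) {
    stop(sprintf("`n` must satisfy 0 <= n <= m (got n = %d, m = %d)", n, m),
         call. = FALSE)
  }
  list(n = n, m = m)
}

# alpha strictly below beta so p = alpha + (beta - alpha) * gamma is strictly
# increasing and invertible.
check_characteristics <- function(alpha, beta) {
  alpha <- check_prob(alpha, "alpha")
  beta <- check_prob(beta, "beta")
  if (alpha >= beta) {
    stop(sprintf(
      "test characteristics must satisfy alpha < beta (got alpha = %g, beta = %g)",
      alpha, beta), call. = FALSE)
  }
  list(alpha = alpha, beta = beta)
}

check_sided <- function(sided) {
  match.arg(sided, c("two.sided", "one.sided"))
}

# Round-half-up, the convention used for all percent-scale table emission
# (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Half-up counterpart of signif() for non-negative values.
signif_half_up <- function(x, digits = 3) {
  out <- x
  nz <- !is.na(x) & x > 0
  e <- floor(log10(x[nz])) - (digits - 1)
  out[nz] <- floor(x[nz] / 10^e + 0.5) * 10^e
  out
}
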