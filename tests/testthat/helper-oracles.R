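# Independent oracles and fixture readers used across the tests.

# Bisection on the binomial tail, independent of the qbeta route used by
# the package. The lower bound solves P(X >= n | m, p) = tail (upper tail
# increasing in p); the upper bound solves P(X <= n | m, p) = tail (lower
# tail decreasing in p).
oracle_lower_p <- function(n, m, tail, tol = 1e-12) {
  if (n == 0) return(0)
  f <- function(p) pbinom(n - 1, m, p, lower.tail = FALSE) - tail
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_upper_p <- function(n, m, tail, tol = 1e-12) {
  if (n == m) return(1)
  f <- function(p) pbinom(n, m, p) - tail
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Published reference tables shipped as TSV fixtures. Rows M = 1..10,
# columns N0..N10 (p-value tables stop at N5); NA above the diagonal.
read_published_table <- function(file) {
  path <- system.file("extdata", file, package = "typicality")
  df <- utils::read.delim(path, fill = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(M = df$M, N = sub("^N", "", colnames(df)[-1]))
  m
}

# Random outcome distributions (representative first, strict maximum) for
# property-style tests.
random_outcome_dist <- function(k) {
  repeat {
    x <- rgamma(k, 1)
    p <- sort(x / sum(x), decreasing = TRUE)
    if (k == 1 || p[1] > max(p[-1])) return(p)
  }
}
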