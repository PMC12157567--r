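test_that("significance mixture and its inverse round-trip to 1e-12", {
  tcs <- list(c(0.05, 1), c(0.01, 0.5), c(0, 1), c(0.3, 0.9))
  gammas <- seq(0, 1, by = 0.05)
  for (tc in tcs) {
    p <- p_from_gamma(gammas, tc[1], tc[2])
    expect_true(all(p >= tc[1] - 1e-15 & p <= tc[2] + 1e-15))
    expect_equal(gamma_from_p(p, tc[1], tc[2]), gammas, tolerance = 1e-12)
  }
  expect_equal(p_from_gamma(0, 0.05, 1), 0.05)
  expect_equal(p_from_gamma(1, 0.05, 1), 1)
  expect_equal(p_from_gamma(0.5, 0.05, 1), 0.525)
})

test_that("typicality inverse clips and rejects degenerate characteristics", {
  expect_equal(gamma_from_p(0.05, 0.05, 1), 0)
  expect_equal(round(gamma_from_p(0.22361, 0.05, 1), 5), 0.18275)
  expect_equal(gamma_from_p(0.03, 0.05, 1), 0) # clipped
  expect_lt(gamma_from_p(0.03, 0.05, 1, clip = FALSE), 0)
  expect_error(gamma_from_p(0.5, 0.5, 0.5), "alpha < beta")
  expect_error(p_from_gamma(0.5, 0.9, 0.1), "alpha < beta")
})

test_that("gamma_c reproduces published anchors and is monotone in N", {
  b22 <- gamma_lower_bound(2, 2) # two-sided default
  expect_equal(round(100 * b22$gamma_c, 1), 11.4)
  b33 <- gamma_lower_bound(3, 3, sided = "one.sided")
  expect_equal(round(100 * b33$gamma_c, 1), 33.5)
  expect_equal(gamma_lower_bound(0, 5)$gamma_c, 0)
  for (m in c(3, 7)) {
    gc <- vapply(0:m, function(n) gamma_lower_bound(n, m)$gamma_c, numeric(1))
    expect_true(all(diff(gc) >= 0))
  }
  expect_warning(gamma_lower_bound(2, 3, beta = 0.9), "conservative")
})

test_that("generated tables match the published tables to 0.1 percent", {
  published <- list(
    two.sided = read_published_table("table1_gammac_two_sided.tsv"),
    one.sided = read_published_table("table2_gammac_one_sided.tsv"))
  for (sided in names(published)) {
    generated <- gamma_table(10, sided = sided)
    ref <- published[[sided]]
    expect_identical(is.na(generated), is.na(ref)) # same triangular shape
    rounded <- floor(generated * 10 + 0.5) / 10    # half-up, percent scale
    expect_equal(rounded[!is.na(ref)], ref[!is.na(ref)], tolerance = 1e-12)
  }
  g1 <- gamma_table(1)
  expect_equal(unname(g1[1, ]), c(0, 0))
})

test_that("one-sided bounds dominate two-sided bounds cell-for-cell", {
  two <- gamma_table(10, sided = "two.sided")
  one <- gamma_table(10, sided = "one.sided")
  keep <- !is.na(two)
  expect_true(all(one[keep] >= two[keep]))
  expect_gte(one[2, "2"], 18.3 - 0.05) # 2-oo-2: 18.3 >= 11.4
})

test_that("unclipped gamma_c exceeds 1 under low sensitivity, clipped never", {
  suppressWarnings(b <- gamma_lower_bound(5, 5, alpha = 0.05, beta = 0.3))
  expect_gt(b$gamma_raw, 1)
  expect_equal(b$gamma_c, 1)
  expect_true(b$clipped)
  expect_true(all(gamma_table(10, sided = "one.sided") <= 100, na.rm = TRUE))
})

test_that("sensitivity curves respond to alpha and beta as expected", {
  # alpha -> 0 limit equals the uncorrected lower bound on p
  s0 <- gamma_sensitivity(2, 2, alpha = 0, beta = 1, sided = "one.sided")
  expect_equal(s0$gamma_c, sqrt(0.05), tolerance = 1e-9)

  s <- gamma_sensitivity(2, 3, alpha = 0.01, beta = 0.5, sided = "one.sided")
  expect_equal(round(s$gamma_c, 4), 0.2558)
  expect_lt(s$gamma_c, 0.5)

  a_grid <- c(0.001, 0.01, 0.05)
  sa <- gamma_sensitivity(2, 3, alpha = a_grid, beta = 1, sided = "one.sided")
  expect_true(all(diff(sa$gamma_c) <= 0)) # non-increasing in alpha

  b_grid <- c(0.5, 0.7, 0.9, 1)
  sb <- gamma_sensitivity(2, 3, alpha = 0.01, beta = b_grid,
                          sided = "one.sided")
  expect_true(all(diff(sb$gamma_c) <= 0)) # lowering beta raises gamma_c

  expect_error(gamma_sensitivity(2, 3, alpha = 0.6, beta = 0.5),
               "alpha < beta")
})
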