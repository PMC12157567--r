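test_that("strict majority threshold generalizes across M", {
  expect_identical(majority_threshold(3), 2L)
  expect_identical(majority_threshold(1), 1L)
  expect_identical(majority_threshold(4), 3L)
  expect_identical(majority_threshold(2), 2L) # even M: ties inconclusive
  expect_error(majority_threshold(0), "m")
})

test_that("sample classification is exclusive and validates counts", {
  expect_identical(classify_sample(c(3, 0), 3), "correct")
  expect_identical(classify_sample(c(1, 2), 3), "incorrect")
  expect_identical(classify_sample(c(1, 1, 1), 3), "inconclusive")
  expect_identical(classify_sample(c(1, 1), 2), "inconclusive") # even-M tie
  expect_error(classify_sample(c(1, 1), 3), "sum to m")
})

test_that("analytic rates match published delta values", {
  r <- rule_rates(c(0.9, 0.1), 3)
  expect_equal(r$incorrect, 0.028, tolerance = 1e-12)

  r4 <- rule_rates(c(0.8, 0.1, 0.05, 0.05), 3)
  expect_equal(r4$incorrect, 0.0425, tolerance = 1e-12)
  expect_equal(r4$inconclusive, 0.0615, tolerance = 1e-12)

  r2 <- rule_rates(c(0.8, 0.15, 0.05), 3)
  expect_equal(r2$incorrect, 0.068, tolerance = 1e-12)

  r1 <- rule_rates(c(0.9, 0.1), 1) # 1-oo-1: delta equals omega
  expect_equal(r1$incorrect, 0.1, tolerance = 1e-12)
  expect_equal(r1$inconclusive, 0)

  r0 <- rule_rates(c(1), 3) # zero-outlier limit
  expect_equal(r0$correct, 1)
  expect_equal(r0$incorrect, 0)
})

test_that("single-outlier error curve follows its closed form", {
  expect_equal(delta_curve(3, 0.1), 0.028, tolerance = 1e-12)
  expect_equal(delta_curve(3, 0.2), 0.104, tolerance = 1e-12)
  expect_equal(delta_curve(3, 0), 0)
  omega <- seq(0, 0.49, by = 0.01)
  expect_equal(delta_curve(3, omega), 3 * omega^2 - 2 * omega^3,
               tolerance = 1e-12)
  expect_equal(delta_curve(1, omega), omega) # 1-oo-1 identity
  for (m in 1:6) {
    expect_true(all(diff(delta_curve(m, omega)) > 0))
  }
  expect_error(delta_curve(3, 0.5), "0.5")
})

test_that("delta reduction of 2-oo-3 over 1-oo-1 peaks at moderate omega", {
  expect_equal(delta_difference(0), 0)
  expect_equal(delta_difference(0.1), 0.1 - 0.028, tolerance = 1e-12)
  omega <- seq(0, 0.499, by = 0.001)
  d <- delta_difference(omega)
  expect_true(all(d >= 0))
  expect_gt(delta_difference(0.21), delta_difference(0.05))
  expect_gt(delta_difference(0.21), delta_difference(0.45))
  # analytic maximizer of w - 3w^2 + 2w^3 is (3 - sqrt(3))/6 ~ 0.2113
  expect_lt(abs(omega[which.max(d)] - (3 - sqrt(3)) / 6), 1e-3)
})

test_that("omega threshold inverts the error curve", {
  w <- omega_threshold(3, 0.05)
  expect_equal(w, 0.1353504, tolerance = 1e-6)
  expect_equal(delta_curve(3, w), 0.05, tolerance = 1e-9)
  expect_equal(omega_threshold(1, 0.05), 0.05, tolerance = 1e-9)
  expect_equal(omega_threshold(3, 0.028), 0.1, tolerance = 1e-8)
  expect_error(omega_threshold(3, 0.9), "delta_target")

  expect_identical(typicality_threshold(3, 0.05), 87L)
})

test_that("enumeration oracle agrees with the analytic rates", {
  expect_error(enumerate_exact(c(0.85, 0.15, 0.05), 3), "sum to 1")
  expect_equal(enumerate_exact(c(0.8, 0.15, 0.05), 3)$incorrect, 0.068,
               tolerance = 1e-12)
  expect_error(enumerate_exact(c(0.3, rep(0.7 / 9, 9)), 9), "guard")

  set.seed(20260929)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    m <- sample(1:6, 1)
    probs <- random_outcome_dist(k)
    a <- rule_rates(probs, m)
    b <- enumerate_exact(probs, m)
    expect_equal(a$correct, b$correct, tolerance = 1e-12)
    expect_equal(a$incorrect, b$incorrect, tolerance = 1e-12)
    expect_equal(a$inconclusive, b$inconclusive, tolerance = 1e-12)
    expect_equal(a$correct + a$incorrect + a$inconclusive, 1,
                 tolerance = 1e-12)
  }
})
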