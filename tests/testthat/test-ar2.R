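test_that("stationarity and pseudoperiodicity flags follow the triangle conditions", {
  f <- ar2_stationary(0.5, -0.2)
  expect_true(f$stationary)
  expect_true(f$pseudoperiodic)   # 0.25 - 0.8 < 0
  expect_false(ar2_stationary(1.0, 0.5)$stationary)
  f0 <- ar2_stationary(0, 0)
  expect_true(f0$stationary)
  expect_true(f0$pseudoperiodic)  # boundary: 0 <= 0
  expect_false(ar2_stationary(1, -0.2)$pseudoperiodic)  # 1 - 0.8 > 0
})

test_that("stationary variance matches the closed form", {
  expect_equal(ar2_stationary_variance(0, 0, 1), 1)
  expect_equal(ar2_stationary_variance(0, -0.5, 0.08), 0.12 / 1.125)
  expect_equal(ar2_stationary_variance(1, -0.8, 0.64), 1.152 / 0.448,
               tolerance = 1e-4)
  expect_error(ar2_stationary_variance(1.5, 0.2, 1), "not stationary")
})

test_that("simulated series have the stationary autocorrelation structure", {
  x <- ar2_simulate(1e5, 0, 0, 1, seed = 41)
  expect_lt(abs(stats::acf(x, plot = FALSE)$acf[2]), 3 / sqrt(1e5))
  y <- ar2_simulate(1e5, 0.5, -0.2, 0.08, mean = 3, seed = 42)
  expect_equal(stats::acf(y, plot = FALSE)$acf[2], 0.5 / 1.2, tolerance = 0.015)
  expect_equal(mean(y), 3, tolerance = 0.05)
  expect_equal(ar2_simulate(10, 0.5, -0.2, 0, mean = 2.5), rep(2.5, 10))
  expect_error(ar2_simulate(10, 1.2, 0.1, 1), "not stationary")
})

test_that("a noiseless recursion is identified exactly", {
  phi1 <- 0.5; phi2 <- -0.2; eta <- 0.7
  x <- numeric(12)
  x[1:2] <- c(4, 2.5)
  for (t in 3:12) x[t] <- eta + phi1 * x[t - 1] + phi2 * x[t - 2]
  fit <- fit_ar2(x)
  expect_equal(unname(coef(fit)[c("phi1", "phi2")]), c(phi1, phi2),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)["intercept"]), eta, tolerance = 1e-8)
})

test_that("coefficient estimates are invariant to shifting the series", {
  x <- ar2_simulate(20, 0.5, -0.2, 0.08, mean = 3, seed = 43)
  f0 <- fit_ar2(x)
  f7 <- fit_ar2(x + 7)
  expect_equal(coef(f0)[c("phi1", "phi2")], coef(f7)[c("phi1", "phi2")],
               tolerance = 1e-10)
  expect_equal(f0$ci, f7$ci, tolerance = 1e-9)
})

test_that("short-series estimates attenuate the dominant coefficients", {
  # T = 20 small-sample bias: the direct coefficient shrinks toward zero, and
  # so does strong delayed density dependence. (Weak delayed dependence can
  # instead overshoot under plain maximum likelihood - see the vignette.)
  set.seed(44)
  est <- t(replicate(300, {
    x <- ar2_simulate(20, 0.5, -0.2, 0.08, mean = 3)
    coef(fit_ar2(x))[c("phi1", "phi2")]
  }))
  expect_lt(mean(est[, "phi1"]), 0.5)
  est2 <- t(replicate(300, {
    x <- ar2_simulate(20, 1, -0.8, 0.08, mean = 3)
    coef(fit_ar2(x))[c("phi1", "phi2")]
  }))
  expect_lt(mean(est2[, "phi1"]), 1)
  expect_gt(mean(est2[, "phi2"]), -0.8)
})

test_that("simulate-then-fit round trip recovers all study coefficient pairs", {
  set.seed(45)
  for (phi1 in c(-1, -0.5, 0, 0.5, 1)) {
    for (phi2 in c(-0.8, -0.5, -0.2)) {
      x <- ar2_simulate(2000, phi1, phi2, 0.08, mean = 3)
      cf <- coef(fit_ar2(x))
      expect_lt(abs(cf[["phi1"]] - phi1), 0.05)
      expect_lt(abs(cf[["phi2"]] - phi2), 0.05)
    }
  }
})

test_that("exact and conditional likelihoods agree on long series", {
  x <- ar2_simulate(3000, 0.5, -0.5, 0.1, mean = 2, seed = 46)
  expect_equal(coef(fit_ar2(x, method = "cml"))[c("phi1", "phi2")],
               coef(fit_ar2(x, method = "exact"))[c("phi1", "phi2")],
               tolerance = 0.01)
})

test_that("degenerate inputs are rejected with actionable messages", {
  expect_error(fit_ar2(c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_ar2(c(1, 2, NA, 4, 5, 6)), "split")
  expect_error(fit_ar2(rep(1, 10)), "degenerate")
  f <- fit_ar2(ar2_simulate(20, 0.5, -0.2, 0.08, seed = 47))
  ci <- confint(f)
  expect_true(all(ci[, "lower"] <= coef(f)[c("phi1", "phi2")] &
                    coef(f)[c("phi1", "phi2")] <= ci[, "upper"]))
})
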