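test_that("intercept-only fit recovers the Lincoln-Petersen probabilities", {
  fit <- fit_capture(~1, counts_to_data(20, 30, 50))
  p <- predict(fit)[1, ]
  expect_equal(p$p1, 50 / 80, tolerance = 1e-7)
  expect_equal(p$p2, 50 / 70, tolerance = 1e-7)
  expect_equal(p$c0, (30 / 80) * (20 / 70), tolerance = 1e-6)
})

test_that("intercept-only fit plus Horvitz-Thompson equals the Petersen estimator", {
  for (cts in list(c(20, 30, 50), c(5, 7, 3), c(100, 1, 40), c(12, 12, 12))) {
    fit <- fit_capture(~1, counts_to_data(cts[1], cts[2], cts[3]))
    N_hat <- horvitz_thompson(never_captured_probability(fit))
    petersen <- (cts[1] + cts[3]) * (cts[2] + cts[3]) / cts[3]
    expect_equal(N_hat, petersen, tolerance = 1e-6)
  }
})

test_that("Poisson-augmented fit agrees with the direct multinomial fit", {
  d <- make_capture_data(50, seed = 4)
  d$x2 <- rnorm(nrow(d))
  direct <- fit_capture(~ weight + x2, d)
  pois <- fit_capture(build_capture_design(d, c("weight", "x2")),
                      method = "poisson")
  expect_equal(coef(direct), coef(pois), tolerance = 1e-6)
  expect_equal(direct$logLik, pois$logLik, tolerance = 1e-8)
})

test_that("direct fit matches an independent multinomial-logit implementation", {
  skip_if_not_installed("nnet")
  d <- make_capture_data(400, seed = 9)
  fit <- fit_capture(~weight, d)
  k <- factor(capture_category(d$w1, d$w2), levels = 1:3)
  mn <- nnet::multinom(k ~ weight, data = d, trace = FALSE)
  cf <- coef(mn)  # rows: categories 2, 3 relative to 1
  expect_equal(unname(fit$delta["weight", "delta1"]),
               unname(cf["3", "weight"] - cf["2", "weight"]), tolerance = 1e-4)
  expect_equal(unname(fit$delta["weight", "delta2"]),
               unname(cf["3", "weight"]), tolerance = 1e-4)
})

test_that("coefficient differences are invariant to the reference category", {
  d <- make_capture_data(200, seed = 5)
  des <- build_capture_design(d, "weight", intercept = TRUE)
  fits <- lapply(1:3, function(r) fit_capture(des, ref = r))
  for (r in 2:3) {
    expect_equal(coef(fits[[1]]), coef(fits[[r]]), tolerance = 1e-8)
  }
})

test_that("the fit recovers the generating coefficient differences", {
  d <- make_capture_data(5000, seed = 2)
  fit <- fit_capture(~ 0 + weight, d)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["delta1.weight"]] - qlogis(0.55)), 3 * se[1])
  expect_lt(abs(coef(fit)[["delta2.weight"]] - qlogis(0.75)), 3 * se[2])
})

test_that("fitted probabilities satisfy the never-capture identity", {
  d <- make_capture_data(150, seed = 6)
  fit <- fit_capture(~ 0 + weight, d)
  f <- fitted(fit)
  expect_true(all(f$p1 > 0 & f$p1 < 1 & f$p2 > 0 & f$p2 < 1))
  expect_equal(never_captured_probability(fit), (1 - f$p1) * (1 - f$p2))
  # probabilities at explicit covariate values
  pn <- predict(fit, newdata = data.frame(weight = 1))
  expect_equal(pn$p1, plogis(coef(fit)[["delta1.weight"]]))
  expect_equal(pn$c0, (1 - pn$p1) * (1 - pn$p2))
})

test_that("degenerate designs raise informative errors", {
  # no (1,1) individuals at all
  d <- data.frame(w1 = c(1, 1, 0, 0), w2 = c(0, 0, 1, 1), weight = 1:4)
  expect_error(fit_capture(~weight, d), "category 3")
  # perfectly separated covariate
  d2 <- counts_to_data(15, 15, 15)
  d2$x <- ifelse(d2$w1 == 1 & d2$w2 == 1, 1, -1)
  err <- tryCatch(fit_capture(~x, d2), error = function(e) e)
  expect_s3_class(err, "capdyn_nonconvergence")
  expect_s3_class(err$trace, "data.frame")  # iteration trace attached
})

test_that("information criteria follow the maximised conditional likelihood", {
  d <- make_capture_data(300, seed = 3)
  fit0 <- fit_capture(~1, d)
  fit1 <- fit_capture(~weight, d)
  expect_equal(AIC(fit1), -2 * fit1$logLik + 2 * fit1$df)
  expect_equal(BIC(fit1), -2 * fit1$logLik + fit1$df * log(fit1$n))
  # weight truly drives capture probability, so it must improve AIC
  expect_lt(AIC(fit1), AIC(fit0))
})

test_that("Bayesian mode returns a penalised-mode Gaussian approximation", {
  d <- make_capture_data(800, seed = 8)
  ml <- fit_capture(~ 0 + weight, d)
  bf <- fit_capture(build_capture_design(d, "weight", intercept = FALSE),
                    bayes = TRUE)
  # weak prior (sd 10): mode is close to the MLE but not identical
  expect_equal(coef(bf), coef(ml), tolerance = 1e-2)
  expect_false(isTRUE(all.equal(coef(bf), coef(ml), tolerance = 1e-12)))
  expect_error(AIC(bf), "penalised")
})
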