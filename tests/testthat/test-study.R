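test_that("coverage is a simple proportion of interval hits", {
  tab <- data.frame(phi1_hat = rep(0.4, 4), phi2_hat = rep(-0.1, 4),
                    lo1 = c(0, 0, 0, 0.6), hi1 = c(1, 1, 1, 0.9),
                    lo2 = -1, hi2 = 0)
  expect_equal(coverage_prop(tab, c(0.5, -0.2))[["phi1"]], 0.75)
  inf <- transform(tab, lo1 = -Inf, hi1 = Inf)
  expect_equal(coverage_prop(inf, c(0.5, -0.2))[["phi1"]], 1)
  out <- transform(tab, lo2 = 5, hi2 = 6)
  expect_equal(coverage_prop(out, c(0.5, -0.2))[["phi2"]], 0)
})

test_that("rmse and joint metrics match their definitions", {
  tab <- data.frame(phi1_hat = 0.5 + c(0.3, 0.4), phi2_hat = -0.2 + c(0.1, -0.1),
                    lo1 = -Inf, hi1 = Inf, lo2 = -Inf, hi2 = Inf)
  truth <- c(0.5, -0.2)
  expect_equal(rmse_metric(tab, truth)[["phi1"]], sqrt((0.09 + 0.16) / 2))
  expect_equal(rmse_metric(tab, truth)[["phi2"]], 0.1)
  tab2 <- data.frame(phi1_hat = 0.6, phi2_hat = -0.3,
                     lo1 = 0, hi1 = 1, lo2 = -1, hi2 = 0)
  expect_equal(joint_metrics(tab2, truth)[["rmse"]], sqrt(0.02))
  expect_equal(joint_metrics(tab2, truth)[["coverage"]], 1)
})

test_that("joint coverage never exceeds either marginal coverage", {
  set.seed(81)
  for (i in 1:20) {
    tab <- data.frame(phi1_hat = rnorm(30), phi2_hat = rnorm(30),
                      lo1 = rnorm(30, -1), hi1 = rnorm(30, 1),
                      lo2 = rnorm(30, -1), hi2 = rnorm(30, 1))
    truth <- rnorm(2, 0, 0.3)
    jm <- joint_metrics(tab, truth)
    cv <- coverage_prop(tab, truth)
    expect_lte(jm[["coverage"]], min(cv))
  }
})

test_that("the coverage estimator is calibrated on exact Gaussian intervals", {
  set.seed(82)
  M <- 400
  n <- 25
  xbar <- rnorm(M, 0, 1 / sqrt(n))
  half <- qnorm(0.975) / sqrt(n)
  tab <- data.frame(phi1_hat = xbar, phi2_hat = xbar,
                    lo1 = xbar - half, hi1 = xbar + half,
                    lo2 = xbar - half, hi2 = xbar + half)
  cov <- coverage_prop(tab, c(0, 0))[["phi1"]]
  expect_lt(abs(cov - 0.95), 3 * sqrt(0.95 * 0.05 / M))
})

test_that("with perfect detection the count method equals the baseline", {
  cfg <- cr_sim_config(0.5, -0.2, 0.08)
  N <- generate_abundance(cfg, seed = 83)
  pop <- generate_weights(N, cfg, seed = 84)
  pop$p1 <- pop$p2 <- 1
  pop$w1 <- pop$w2 <- 1L
  ds <- observe_population(list(pop = pop, N = N, config = cfg))
  fits <- estimate_all_methods(ds, methods = c("baseline", "obs_count"),
                               variants = "A")
  expect_equal(coef(fits[["baseline.A"]]), coef(fits[["obs_count.A"]]),
               tolerance = 1e-12)
})

test_that("homogeneous capture makes the capture-model chain an offset of the counts", {
  cfg <- cr_sim_config(0.5, -0.2, 0.08, target_mean_abundance = 400)
  N <- generate_abundance(cfg, seed = 85)
  pop <- generate_weights(N, cfg, seed = 86)
  pop$weight <- 1  # identical covariate: shared capture probabilities
  pop <- assign_capture_histories(pop, cfg, seed = 87)
  ds <- observe_population(list(pop = pop, N = N, config = cfg))
  fits <- estimate_all_methods(ds, methods = c("cr_fit", "obs_count"),
                               variants = "A")
  # HT series = n_t / (1 - c0_hat): a constant log offset, so identical phi
  expect_equal(coef(fits[["cr_fit.A"]])[c("phi1", "phi2")],
               coef(fits[["obs_count.A"]])[c("phi1", "phi2")],
               tolerance = 1e-6)
})

test_that("one replicate yields one AR(2) fit per method and variant", {
  cfg <- cr_sim_config(0.5, -0.2, 0.08)
  ds <- simulate_cr_series(cfg, seed = 88)
  fits <- estimate_all_methods(ds, variants = c("A", "P"),
                               external_c0 = function(d)
                                 rep(0.2, nrow(d$records)))
  expect_setequal(names(fits),
                  c(t(outer(c("baseline", "obs_count", "cr_fit",
                              "cr_external_hook"), c("A", "P"), paste,
                            sep = "."))))
  expect_s3_class(fits[["cr_fit.P"]], "ar2_fit")
  expect_identical(fits[["cr_fit.P"]]$variant, "P")
})

test_that("the study driver aggregates cells and averages deterministically", {
  res <- run_study(phi1 = c(0, 0.5), phi2 = -0.5, sigma2_eps = 0.08,
                   M = 4L, seed = 89, variants = "A")
  expect_s3_class(res, "cr_study")
  expect_equal(nrow(res$cells), 2 * 3)  # 2 combos x 3 methods
  expect_true(all(res$cells$cov_phi1 >= 0 & res$cells$cov_phi1 <= 1))
  expect_true(all(res$cells$rmse_joint >= 0))
  expect_true(all(res$cells$cov_joint <=
                    pmin(res$cells$cov_phi1, res$cells$cov_phi2)))
  expect_equal(nrow(res$averages), 3)
  res2 <- run_study(phi1 = c(0, 0.5), phi2 = -0.5, sigma2_eps = 0.08,
                    M = 4L, seed = 89, variants = "A")
  expect_identical(res$cells, res2$cells)
})

test_that("uncertainty propagation collapses to the plug-in fit without covariance", {
  cfg <- cr_sim_config(0.5, -0.2, 0.08)
  ds <- simulate_cr_series(cfg, seed = 90)
  fits <- estimate_all_methods(ds, methods = "cr_fit", variants = "A")
  cfit <- attr(fits, "capture_fit")
  pu0 <- propagate_uncertainty(cfit, ds, B = 5, seed = 91, zero_covariance = TRUE)
  expect_equal(unname(pu0$sd), c(0, 0))
  expect_equal(unname(pu0$draws[1, ]),
               unname(coef(fits[["cr_fit.A"]])[c("phi1", "phi2")]))
  pu1 <- propagate_uncertainty(cfit, ds, B = 1, seed = 92)
  expect_equal(nrow(pu1$draws), 1L)
})
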