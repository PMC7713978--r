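# Simulator of two-session capture-recapture sampling over AR(2) population
# dynamics. The defaults are the study conditions used throughout: T = 20
# seasons, expected abundance 20 per time point, session capture
# probabilities 0.55 and 0.75 at unit scaled weight, lognormal body weights
# whose time-varying mean models changing detectability.

#' Simulation configuration
#'
#' Bundles the parameters of one simulation scenario. Defaults are the
#' calibrated study conditions; only the AR(2) parameters normally vary.
#'
#' @param phi1,phi2 AR(2) coefficients of the log-abundance process (must be
#'   stationary).
#' @param sigma2_eps Innovation (process) variance of the AR(2) process.
#' @param T Series length in time points.
#' @param target_mean_abundance Expected abundance per time point; the AR(2)
#'   offset is chosen as `ln(target) - Var(ln N_t)/2` so the lognormal mean
#'   of `N_t` equals the target regardless of the process variance.
#' @param p1,p2 Session capture probabilities of an individual with scaled
#'   weight exactly 1.
#' @param sigma_w Weight spread multiplier: individual weights are lognormal
#'   with log-sd `ln(sigma_w)` around the time-point mean.
#' @param mu_w_mean,mu_w_sd The time-point mean weight `mu_t` is lognormal
#'   with log-mean `ln(mu_w_mean)` and log-sd `ln(mu_w_sd)`.
#' @param M Number of replicate series in a scenario.
#' @return A list of class `"cr_sim_config"`.
#' @export
cr_sim_config <- function(phi1, phi2, sigma2_eps, T = 20L,
                          target_mean_abundance = 20,
                          p1 = 0.55, p2 = 0.75, sigma_w = 1.2,
                          mu_w_mean = 30, mu_w_sd = 5, M = 200L) {
  if (!ar2_stationary(phi1, phi2)$stationary) {
    stop("(phi1, phi2) must be stationary", call. = FALSE)
  }
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, sigma_w > 1, sigma2_eps >= 0,
            T >= 5, target_mean_abundance > 0, M >= 1)
  structure(list(phi1 = phi1, phi2 = phi2, sigma2_eps = sigma2_eps,
                 T = as.integer(T),
                 target_mean_abundance = target_mean_abundance,
                 p1 = p1, p2 = p2, sigma_w = sigma_w,
                 mu_w_mean = mu_w_mean, mu_w_sd = mu_w_sd,
                 M = as.integer(M)),
            class = "cr_sim_config")
}

#' @export
print.cr_sim_config <- function(x, ...) {
  cat("Capture-recapture simulation scenario\n")
  cat(sprintf("  AR(2): phi1 = %g, phi2 = %g, sigma2_eps = %g, T = %d\n",
              x$phi1, x$phi2, x$sigma2_eps, x$T))
  cat(sprintf("  E(N_t) = %g; p1 = %g, p2 = %g at scaled weight 1; M = %d\n",
              x$target_mean_abundance, x$p1, x$p2, x$M))
  invisible(x)
}

# Deterministic substream seeds: mix the master seed with stage indices so
# every (scenario, replicate, stage) is individually reproducible. Kept below
# 2^31 and exact in double arithmetic.
derive_seed <- function(master, ...) {
  s <- as.double(master %% 2147483647)
  for (x in c(...)) {
    s <- (s * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Generate a true abundance series
#'
#' Simulates the log-abundance AR(2) process with the variance-corrected
#' offset (stationary mean `ln(target) - Var(ln N_t)/2`, so `E(N_t)` equals
#' the target by the lognormal mean identity), exponentiates, and rounds to
#' the nearest integer. Rounded values below 1 are clamped to 1 so the log
#' abundance stays defined; this matters only at the largest process
#' variances and the number of clamped points is recorded.
#'
#' @param config A `"cr_sim_config"`.
#' @param seed Optional integer seed.
#' @return Integer vector `N_t` of length `config$T`, with attributes
#'   `log_N_true` (the unrounded log series) and `n_clamped`.
#' @export
generate_abundance <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  g0 <- if (config$sigma2_eps == 0) 0 else
    ar2_stationary_variance(config$phi1, config$phi2, config$sigma2_eps)
  mu <- log(config$target_mean_abundance) - g0 / 2
  lnN <- ar2_simulate(config$T, config$phi1, config$phi2, config$sigma2_eps,
                      mean = mu)
  N <- as.integer(round(exp(lnN)))
  clamped <- sum(N < 1L)
  N[N < 1L] <- 1L
  structure(N, log_N_true = lnN, n_clamped = clamped)
}

#' Generate scaled individual weights
#'
#' Each time point gets a lognormal mean weight `mu_t`; each individual alive
#' at that time point gets a lognormal weight around it. All weights of the
#' series are then divided by their pooled sample standard deviation, giving
#' a dimensionless covariate with pooled sd exactly 1. Weight acts as a proxy
#' for detectability, and the time-varying mean makes detectability drift
#' between time points.
#'
#' @param N Integer abundance per time point.
#' @param config A `"cr_sim_config"`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `time`, `weight_raw`, `weight` (scaled).
#' @export
generate_weights <- function(N, config, seed = NULL) {
  stopifnot(inherits(config, "cr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  T <- length(N)
  mu_t <- stats::rlnorm(T, log(config$mu_w_mean), log(config$mu_w_sd))
  raw <- stats::rlnorm(sum(N), rep(log(mu_t), N), log(config$sigma_w))
  data.frame(time = rep(seq_len(T), N),
             weight_raw = raw,
             weight = raw / stats::sd(raw))
}

#' Assign two-session capture histories
#'
#' Sets the coefficient differences to `delta1 = logit(p1)` and
#' `delta2 = logit(p2)`, so an individual with scaled weight exactly 1 has
#' session probabilities `(p1, p2)`; each individual's probabilities are
#' `plogis(delta1 * weight)` and `plogis(delta2 * weight)` (weight is the
#' sole covariate, no intercept), and the two sessions are sampled
#' independently (Mth model).
#'
#' @param pop Data frame with a scaled `weight` column (see
#'   [generate_weights()]).
#' @param config A `"cr_sim_config"`.
#' @param seed Optional integer seed.
#' @return `pop` with added columns `p1`, `p2`, `w1`, `w2`.
#' @export
assign_capture_histories <- function(pop, config, seed = NULL) {
  stopifnot(inherits(config, "cr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  d1 <- stats::qlogis(config$p1)
  d2 <- stats::qlogis(config$p2)
  pop$p1 <- stats::plogis(d1 * pop$weight)
  pop$p2 <- stats::plogis(d2 * pop$weight)
  n <- nrow(pop)
  pop$w1 <- stats::rbinom(n, 1L, pop$p1)
  pop$w2 <- stats::rbinom(n, 1L, pop$p2)
  pop
}

#' Reduce a simulated population to its observed dataset
#'
#' Drops never-captured individuals (category 0) and returns the observed
#' records together with the retained truth, as produced by a real trapping
#' study plus the simulator's bookkeeping.
#'
#' @param sim A `"cr_sim"` from [simulate_cr_series()], or a list with
#'   elements `pop` (individual table with `w1`, `w2`, `time`) and `N`.
#' @return A list of class `"cr_dataset"`: `records` (captured individuals
#'   with `id`, `site`, `time`, `weight`, `w1`, `w2`), `n_t` observed counts,
#'   and `truth` (`N_t`, `log_N_true`, AR parameters when known).
#' @export
observe_population <- function(sim) {
  pop <- sim$pop
  keep <- (pop$w1 + pop$w2) > 0
  rec <- pop[keep, , drop = FALSE]
  T <- length(sim$N)
  rec$id <- sprintf("ind%05d", seq_len(nrow(rec)))
  rec$site <- if (!is.null(sim$site)) sim$site else "sim"
  rec <- rec[, c("id", "site", "time", "weight", "w1", "w2",
                 intersect(c("weight_raw", "p1", "p2"), names(rec)))]
  structure(list(records = rec,
                 n_t = tabulate(rec$time, T),
                 truth = list(N = as.integer(sim$N),
                              log_N_true = attr(sim$N, "log_N_true"),
                              config = sim$config),
                 pop = pop),
            class = "cr_dataset")
}

#' @export
print.cr_dataset <- function(x, ...) {
  cat("Simulated capture-recapture dataset:",
      nrow(x$records), "captured of", sum(x$truth$N), "individuals over",
      length(x$n_t), "time points\n")
  invisible(x)
}

#' Simulate one capture-recapture series
#'
#' Runs the full generative chain - AR(2) abundance, weights, capture
#' histories, observation - for a single replicate.
#'
#' @param config A `"cr_sim_config"`.
#' @param seed Integer seed; stage-level substreams are derived from it so
#'   each stage is independently reproducible.
#' @param site Site label attached to the records.
#' @return A `"cr_dataset"` (see [observe_population()]).
#' @export
simulate_cr_series <- function(config, seed, site = "sim") {
  N <- generate_abundance(config, seed = derive_seed(seed, 1L))
  pop <- generate_weights(N, config, seed = derive_seed(seed, 2L))
  pop <- assign_capture_histories(pop, config, seed = derive_seed(seed, 3L))
  observe_population(list(pop = pop, N = N, config = config, site = site))
}

#' Simulate a full scenario of replicate series
#'
#' @param config A `"cr_sim_config"` (its `M` is the number of replicates).
#' @param seed Master integer seed; per-replicate substreams are derived
#'   deterministically, so any replicate can be regenerated on its own.
#' @return List of `M` `"cr_dataset"` objects.
#' @export
simulate_cr_scenario <- function(config, seed) {
  stopifnot(inherits(config, "cr_sim_config"))
  lapply(seq_len(config$M), function(m)
    simulate_cr_series(config, seed = derive_seed(seed, 100L, m),
                       site = sprintf("rep%03d", m)))
}
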