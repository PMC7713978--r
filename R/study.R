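# Simulation-study driver: compare density-dependence estimators that use
# capture-history information (capture model + Horvitz-Thompson abundance)
# against a baseline fitted to the true log abundance and a naive estimator
# fitted to observed log counts, in two variants - AR(2) on the log series
# directly (A) or on posterior-mean Poisson log rates (P).

#' Fit every estimation method to one simulated dataset
#'
#' @param dataset A `"cr_dataset"` with truth attached.
#' @param methods Subset of `c("baseline", "cr_fit", "obs_count")`.
#'   `baseline` fits the AR(2) model to the true log abundance, `cr_fit` runs
#'   the capture model / Horvitz-Thompson / AR(2) chain, `obs_count` fits the
#'   AR(2) model to observed log counts.
#' @param variants `"A"` (log series), `"P"` (posterior-mean Poisson log
#'   rates via [fit_poisson_lograte()]; Horvitz-Thompson estimates are
#'   rounded to the nearest positive integer to serve as counts), or both.
#' @param external_c0 Optional hook for an externally fitted capture model:
#'   a numeric vector of never-capture probabilities, one per captured
#'   individual, or a function of the dataset returning one. Adds method
#'   `"cr_external_hook"`.
#' @param capture_formula Capture-model formula; the default `~ 0 + weight`
#'   matches the simulator's generative model.
#' @return A list of `"ar2_fit"` objects named `<method>.<variant>`.
#' @export
estimate_all_methods <- function(dataset,
                                 methods = c("baseline", "cr_fit", "obs_count"),
                                 variants = c("A", "P"),
                                 external_c0 = NULL,
                                 capture_formula = ~ 0 + weight) {
  stopifnot(inherits(dataset, "cr_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  variants <- match.arg(variants, several.ok = TRUE)
  if (any(dataset$n_t == 0L)) {
    stop("time point(s) ", paste(which(dataset$n_t == 0L), collapse = ", "),
         " have zero captures; replicate is degenerate for count-based methods",
         call. = FALSE)
  }
  out <- list()
  series <- list()
  if ("baseline" %in% methods) {
    series$baseline <- list(logx = log(dataset$truth$N), counts = dataset$truth$N)
  }
  if ("obs_count" %in% methods) {
    series$obs_count <- list(logx = log(dataset$n_t), counts = dataset$n_t)
  }
  if ("cr_fit" %in% methods) {
    cfit <- fit_capture(capture_formula, dataset$records)
    ab <- abundance_series(dataset$records, cfit,
                           time_points = seq_along(dataset$n_t))
    series$cr_fit <- list(logx = ab$log_N_hat,
                          counts = pmax(1L, as.integer(round(ab$N_hat))),
                          capture_fit = cfit)
  }
  if (!is.null(external_c0)) {
    c0 <- if (is.function(external_c0)) external_c0(dataset) else external_c0
    if (length(c0) != nrow(dataset$records)) {
      stop("external_c0 must give one never-capture probability per captured individual",
           call. = FALSE)
    }
    wts <- 1 / (1 - c0)
    Nh <- as.numeric(tapply(wts, factor(dataset$records$time,
                                        levels = seq_along(dataset$n_t)), sum))
    series$cr_external_hook <- list(logx = log(Nh),
                                    counts = pmax(1L, as.integer(round(Nh))))
  }
  for (nm in names(series)) {
    if ("A" %in% variants) {
      out[[paste0(nm, ".A")]] <- fit_ar2(series[[nm]]$logx, variant = "A")
    }
    if ("P" %in% variants) {
      lam <- fit_poisson_lograte(series[[nm]]$counts)$lambda_hat
      out[[paste0(nm, ".P")]] <- fit_ar2(lam, variant = "P")
    }
  }
  attr(out, "capture_fit") <- series$cr_fit$capture_fit
  out
}

#' Collect AR(2) fits into a replicate table
#'
#' @param fits List of `"ar2_fit"` objects (one per replicate, same method).
#' @return Data frame with columns `phi1_hat`, `phi2_hat` and the 95%
#'   interval bounds `lo1`, `hi1`, `lo2`, `hi2`.
#' @export
ar2_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(phi1_hat = unname(f$coefficients["phi1"]),
               phi2_hat = unname(f$coefficients["phi2"]),
               lo1 = f$ci["phi1", "lower"], hi1 = f$ci["phi1", "upper"],
               lo2 = f$ci["phi2", "lower"], hi2 = f$ci["phi2", "upper"])
  }))
}

#' Interval coverage of the true AR coefficients
#'
#' @param tab Replicate table from [ar2_fit_table()].
#' @param truth Numeric `c(phi1, phi2)`.
#' @return Named vector: fraction of replicates whose 95% interval contains
#'   the true value, per coefficient.
#' @export
coverage_prop <- function(tab, truth) {
  c(phi1 = mean(tab$lo1 <= truth[1] & truth[1] <= tab$hi1),
    phi2 = mean(tab$lo2 <= truth[2] & truth[2] <= tab$hi2))
}

#' Root mean-squared error of the AR coefficient estimates
#'
#' @inheritParams coverage_prop
#' @return Named vector of `sqrt(mean((phi_hat - phi)^2))` per coefficient.
#' @export
rmse_metric <- function(tab, truth) {
  c(phi1 = sqrt(mean((tab$phi1_hat - truth[1])^2)),
    phi2 = sqrt(mean((tab$phi2_hat - truth[2])^2)))
}

#' Joint coverage and joint RMSE of both AR coefficients
#'
#' Joint coverage is the fraction of replicates where both intervals contain
#' their true values (never larger than either marginal coverage); joint RMSE
#' is `sqrt(mean(sum_k (phi_hat_k - phi_k)^2))`.
#'
#' @inheritParams coverage_prop
#' @return Named vector `c(coverage, rmse)`.
#' @export
joint_metrics <- function(tab, truth) {
  hit <- (tab$lo1 <= truth[1] & truth[1] <= tab$hi1) &
    (tab$lo2 <= truth[2] & truth[2] <= tab$hi2)
  c(coverage = mean(hit),
    rmse = sqrt(mean((tab$phi1_hat - truth[1])^2 + (tab$phi2_hat - truth[2])^2)))
}

#' Run the method-comparison simulation study
#'
#' For every combination of the AR(2) coefficients and every process-variance
#' level, simulates `M` replicate capture-recapture series, fits the selected
#' methods and variants, and summarises interval coverage and RMSE per cell
#' plus averages across the coefficient combinations at each variance level.
#' Replicates where any time point has zero captures, or where a fit fails,
#' are excluded from that cell's averages and counted in `failures`.
#'
#' @param phi1,phi2 Vectors of AR coefficients; their cross product gives the
#'   coefficient combinations.
#' @param sigma2_eps Vector of process-variance levels.
#' @param M Replicates per cell.
#' @param seed Master seed; per-replicate substreams are derived from it.
#' @param methods,variants Passed to [estimate_all_methods()].
#' @param T,target_mean_abundance,... Further scenario parameters passed to
#'   [cr_sim_config()].
#' @param progress Print a line per cell.
#' @return An object of class `"cr_study"`: list with `cells` (tidy data
#'   frame: `method`, `variant`, `phi1`, `phi2`, `sigma2`, `M`, `cov_phi1`,
#'   `cov_phi2`, `cov_joint`, `rmse_phi1`, `rmse_phi2`, `rmse_joint`,
#'   `bias_phi1`, `bias_phi2` (mean signed estimation errors), `failures`)
#'   and `averages` (the same metrics averaged over coefficient
#'   combinations, per `sigma2` x method x variant).
#' @export
run_study <- function(phi1 = c(-1, -0.5, 0, 0.5, 1),
                      phi2 = c(-0.8, -0.5, -0.2),
                      sigma2_eps = c(0.04, 0.08, 0.16, 0.32, 0.64),
                      M = 200L, seed = 1L,
                      methods = c("baseline", "cr_fit", "obs_count"),
                      variants = "A",
                      T = 20L, target_mean_abundance = 20,
                      progress = FALSE, ...) {
  grid <- expand.grid(phi1 = phi1, phi2 = phi2, sigma2 = sigma2_eps,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- cr_sim_config(grid$phi1[g], grid$phi2[g], grid$sigma2[g],
                         T = T, target_mean_abundance = target_mean_abundance,
                         M = M, ...)
    res <- run_cell(cfg, seed = derive_seed(seed, 1000L, g),
                    methods = methods, variants = variants)
    truth <- c(grid$phi1[g], grid$phi2[g])
    for (key in names(res$tables)) {
      tab <- res$tables[[key]]
      mv <- strsplit(key, ".", fixed = TRUE)[[1]]
      cells[[length(cells) + 1L]] <- data.frame(
        method = mv[1], variant = mv[2],
        phi1 = truth[1], phi2 = truth[2], sigma2 = grid$sigma2[g],
        M = nrow(tab),
        cov_phi1 = coverage_prop(tab, truth)[["phi1"]],
        cov_phi2 = coverage_prop(tab, truth)[["phi2"]],
        cov_joint = joint_metrics(tab, truth)[["coverage"]],
        rmse_phi1 = rmse_metric(tab, truth)[["phi1"]],
        rmse_phi2 = rmse_metric(tab, truth)[["phi2"]],
        rmse_joint = joint_metrics(tab, truth)[["rmse"]],
        bias_phi1 = mean(tab$phi1_hat) - truth[1],
        bias_phi2 = mean(tab$phi2_hat) - truth[2],
        failures = res$failures)
    }
    if (progress) {
      message(sprintf("cell %d/%d (phi1=%g, phi2=%g, sigma2=%g): %d failures",
                      g, nrow(grid), truth[1], truth[2], grid$sigma2[g],
                      res$failures))
    }
  }
  cells <- do.call(rbind, cells)
  metr <- c("cov_phi1", "cov_phi2", "cov_joint",
            "rmse_phi1", "rmse_phi2", "rmse_joint")
  averages <- stats::aggregate(cells[metr],
                               by = cells[c("method", "variant", "sigma2")],
                               FUN = mean)
  averages <- averages[order(averages$sigma2, averages$method, averages$variant), ]
  structure(list(cells = cells, averages = averages,
                 M = M, seed = seed, methods = methods, variants = variants),
            class = "cr_study")
}

# One scenario cell: simulate M replicates, fit all methods, pool tables.
run_cell <- function(config, seed, methods, variants) {
  acc <- list()
  failures <- 0L
  for (m in seq_len(config$M)) {
    ds <- simulate_cr_series(config, seed = derive_seed(seed, m))
    fits <- tryCatch(
      estimate_all_methods(ds, methods = methods, variants = variants),
      error = function(e) NULL)
    if (is.null(fits)) { failures <- failures + 1L; next }
    for (key in names(fits)) acc[[key]][[length(acc[[key]]) + 1L]] <- fits[[key]]
  }
  if (failures > 0.1 * config$M) {
    warning(sprintf("scenario (phi1=%g, phi2=%g, sigma2=%g): %d of %d replicates failed",
                    config$phi1, config$phi2, config$sigma2_eps,
                    failures, config$M), call. = FALSE)
  }
  list(tables = lapply(acc, ar2_fit_table), failures = failures)
}

#' @export
print.cr_study <- function(x, digits = 3, ...) {
  cat("Capture-recapture density-dependence study:",
      length(unique(paste(x$cells$phi1, x$cells$phi2))), "coefficient combinations x",
      length(unique(x$cells$sigma2)), "variance level(s), M =", x$M, "\n\n")
  cat("Averages across coefficient combinations:\n")
  av <- x$averages
  av[sapply(av, is.numeric)] <- lapply(av[sapply(av, is.numeric)], round, digits)
  print(av, row.names = FALSE)
  invisible(x)
}

#' Propagate capture-model uncertainty into the AR coefficients
#'
#' Draws `B` coefficient vectors from the capture fit's Gaussian
#' approximation, recomputes the Horvitz-Thompson abundance series and refits
#' the AR(2) model for each draw, and reports the spread of the resulting
#' coefficient estimates. This measures how much first-stage (capture-model)
#' uncertainty contributes to second-stage (density-dependence) uncertainty.
#'
#' @param fit A `"capture_fit"`.
#' @param dataset The `"cr_dataset"` the model was fitted to.
#' @param B Number of posterior draws.
#' @param seed Optional integer seed.
#' @param zero_covariance If `TRUE`, draws collapse to the point estimate
#'   (every refit is the plug-in fit; the spread is exactly zero). Mainly a
#'   consistency check.
#' @return List of class `"cr_uncertainty"`: `sd` (spread of `phi1_hat`,
#'   `phi2_hat` across draws), `draws` (B x 2 matrix), `B`.
#' @export
propagate_uncertainty <- function(fit, dataset, B = 200L, seed = NULL,
                                  zero_covariance = FALSE) {
  stopifnot(inherits(fit, "capture_fit"), inherits(dataset, "cr_dataset"))
  if (!is.null(seed)) set.seed(seed)
  theta <- fit$theta
  q <- length(theta)
  if (zero_covariance) {
    Th <- matrix(theta, B, q, byrow = TRUE)
  } else {
    R <- tryCatch(chol(fit$vcov_theta), error = function(e)
      stop("capture-fit covariance is degenerate; cannot draw from the ",
           "Gaussian approximation", call. = FALSE))
    Th <- matrix(theta, B, q, byrow = TRUE) +
      matrix(stats::rnorm(B * q), B, q) %*% R
  }
  z <- fit$design$z
  L <- delta_transform(ncol(z), fit$ref)
  tf <- factor(dataset$records$time, levels = seq_along(dataset$n_t))
  draws <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("phi1_hat", "phi2_hat")))
  for (b in seq_len(B)) {
    delta <- matrix(L %*% Th[b, ], ncol = 2)
    p1 <- stats::plogis(drop(z %*% delta[, 1]))
    p2 <- stats::plogis(drop(z %*% delta[, 2]))
    wts <- 1 / (1 - (1 - p1) * (1 - p2))
    Nh <- as.numeric(tapply(wts, tf, sum))
    f <- fit_ar2(log(Nh))
    draws[b, ] <- f$coefficients[c("phi1", "phi2")]
  }
  structure(list(sd = apply(draws, 2, stats::sd), draws = draws, B = B),
            class = "cr_uncertainty")
}

#' @export
print.cr_uncertainty <- function(x, digits = 4, ...) {
  cat("Capture-model uncertainty propagated through", x$B, "posterior draws\n")
  cat("spread (sd) of AR coefficient estimates across draws:\n")
  print(round(x$sd, digits))
  invisible(x)
}
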