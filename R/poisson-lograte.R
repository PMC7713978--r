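# Poisson-log-normal latent rate model for count series:
#   y_t ~ Poisson(exp(beta0 + e_t)),  e_t iid N(0, 1/kappa_e).
# The marginal likelihood integrates each e_t out numerically; the posterior
# mean log rates lambda_hat_t = beta0 + E(e_t | y_t) are the "P variant"
# series the AR(2) model is fitted to.

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) by Golub-Welsch.
gauss_hermite <- function(k) {
  J <- matrix(0, k, k)
  off <- sqrt(seq_len(k - 1) / 2)
  J[cbind(1:(k - 1), 2:k)] <- off
  J[cbind(2:k, 1:(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

.gh30 <- gauss_hermite(30L)

# Log of integral_u Poisson(y; exp(b0+u)) N(u; 0, sig2) du by adaptive GH:
# recentre the rule at the mode of the integrand, rescale by its curvature.
pln_log_marginal <- function(y, b0, sig2, gh = .gh30) {
  # mode of h(u) = y(b0+u) - exp(b0+u) - u^2/(2 sig2) by Newton
  u <- 0
  for (it in 1:50) {
    g <- y - exp(b0 + u) - u / sig2
    h <- -exp(b0 + u) - 1 / sig2
    step <- g / h
    u <- u - step
    if (abs(step) < 1e-12) break
  }
  s <- 1 / sqrt(exp(b0 + u) + 1 / sig2)
  uu <- u + sqrt(2) * s * gh$nodes
  logf <- y * (b0 + uu) - exp(b0 + uu) - lgamma(y + 1) -
    0.5 * uu^2 / sig2 - 0.5 * log(2 * pi * sig2)
  m <- max(logf)
  lw <- log(sqrt(2) * s) + log(gh$weights) + gh$nodes^2 + logf
  mm <- max(lw)
  log(sum(exp(lw - mm))) + mm
}

# Posterior mean of e_t given y_t at (b0, sig2), same adaptive rule.
pln_posterior_mean <- function(y, b0, sig2, gh = .gh30) {
  u <- 0
  for (it in 1:50) {
    g <- y - exp(b0 + u) - u / sig2
    h <- -exp(b0 + u) - 1 / sig2
    u <- u - g / h
    if (abs(g / h) < 1e-12) break
  }
  s <- 1 / sqrt(exp(b0 + u) + 1 / sig2)
  uu <- u + sqrt(2) * s * gh$nodes
  logf <- y * (b0 + uu) - exp(b0 + uu) - 0.5 * uu^2 / sig2
  w <- exp(logf - max(logf) + gh$nodes^2) * gh$weights
  sum(w * uu) / sum(w)
}

#' Fit a Poisson-log-normal latent rate model to a count series
#'
#' Models counts as `y_t ~ Poisson(exp(beta0 + e_t))` with iid Gaussian
#' time effects `e_t ~ N(0, 1/kappa_e)`. The marginal likelihood is maximised
#' over `(beta0, kappa_e)` with each random effect integrated out by 30-point
#' adaptive Gauss-Hermite quadrature, and the fitted log rates are the
#' posterior means `lambda_hat_t = beta0 + E(e_t | y_t)`.
#'
#' @param y Nonnegative integer counts, length >= 5, not all zero.
#' @return An object of class `"pois_lograte_fit"` with components `beta0`,
#'   `kappa_e` (random-effect precision), `sigma2_e`, `lambda_hat` (posterior
#'   mean log rates), `logLik`, `T`.
#' @examples
#' fit_poisson_lograte(c(12, 30, 55, 18, 9, 25, 40))$lambda_hat
#' @export
fit_poisson_lograte <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || any(y < 0) || any(y != floor(y))) {
    stop("`y` must be nonnegative integer counts without missing values",
         call. = FALSE)
  }
  if (length(y) < 5) stop("need at least 5 time points", call. = FALSE)
  if (all(y == 0)) stop("all-zero count series: the log rate is degenerate",
                        call. = FALSE)
  negll <- function(par) {
    b0 <- par[1]
    sig2 <- exp(par[2])
    -sum(vapply(y, pln_log_marginal, numeric(1), b0 = b0, sig2 = sig2))
  }
  start <- c(log(mean(y) + 0.5), log(max(stats::var(log(y + 0.5)), 1e-3)))
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(-20, -12), upper = c(20, 6),
                      control = list(factr = 1e4))
  b0 <- opt$par[1]
  sig2 <- exp(opt$par[2])
  lam <- b0 + vapply(y, pln_posterior_mean, numeric(1), b0 = b0, sig2 = sig2)
  structure(list(beta0 = b0, kappa_e = 1 / sig2, sigma2_e = sig2,
                 lambda_hat = lam, logLik = -opt$value, T = length(y),
                 convergence = opt$convergence),
            class = "pois_lograte_fit")
}

#' @export
print.pois_lograte_fit <- function(x, digits = 4, ...) {
  cat("Poisson-log-normal latent rate fit, T =", x$T, "\n")
  cat(sprintf("  beta0 = %.*f   kappa_e = %.4g   logLik = %.*f\n",
              digits, x$beta0, x$kappa_e, digits, x$logLik))
  cat("posterior mean log rates:\n")
  print(round(x$lambda_hat, digits))
  invisible(x)
}

#' @export
coef.pois_lograte_fit <- function(object, ...) {
  c(beta0 = object$beta0, kappa_e = object$kappa_e)
}

#' @export
fitted.pois_lograte_fit <- function(object, ...) object$lambda_hat
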