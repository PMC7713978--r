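# Conditional multinomial likelihood for the two-session Mth model.
#
# Only differences of the category coefficients are identifiable, so one
# category is fixed at zero (the reference) and the two free coefficient
# vectors are estimated by Newton-Raphson on the conditional multinomial
# log likelihood. The session capture probabilities are recovered from the
# coefficient differences
#   logit(p1) = sum_r (gamma_3r - gamma_2r) z_r,
#   logit(p2) = sum_r (gamma_3r - gamma_1r) z_r.

#' Fit the two-session Mth capture-probability model
#'
#' Maximises the conditional multinomial likelihood of the three observable
#' capture categories for individuals caught at least once, with category
#' probabilities softmax-linked to individual covariates. Session capture
#' probabilities and the never-capture probability of every captured
#' individual are recovered from the estimated coefficient differences; the
#' coefficient differences themselves are invariant to the choice of
#' reference category.
#'
#' @param x A `"capture_design"` from [build_capture_design()], or a one-sided
#'   formula naming covariate columns (e.g. `~ weight` or `~ 0 + weight` for
#'   no intercept) evaluated in `data`.
#' @param data Data frame of captured individuals (formula interface only).
#' @param method `"multinomial"` (default) fits the conditional multinomial
#'   logit directly by Newton-Raphson; `"poisson"` fits the augmented count
#'   model of [expand_to_poisson()] with per-individual auxiliary intercepts
#'   via [stats::glm()]. Both maximise the same likelihood and agree in the
#'   coefficient differences; the Poisson route carries n nuisance parameters
#'   and exists mainly as an internal cross-check.
#' @param ref Reference category fixed at zero, one of 1, 2, 3
#'   (multinomial method only).
#' @param bayes Logical; if `TRUE`, adds a weak zero-mean Gaussian prior
#'   (sd `prior_sd`) on every free coefficient and returns a Gaussian
#'   posterior approximation centred at the penalised mode. Likelihood-based
#'   information criteria are then unavailable.
#' @param prior_sd Prior standard deviation used when `bayes = TRUE`.
#' @param tol_grad,tol_loglik,max_iter Newton convergence controls: stop when
#'   the gradient norm falls below `tol_grad` or the relative log-likelihood
#'   change below `tol_loglik`; error after `max_iter` iterations.
#' @param ... Passed between methods.
#' @return An object of class `"capture_fit"` with components `delta`
#'   (v x 2 matrix of coefficient differences: column `delta1` drives
#'   session-1, `delta2` session-2 capture probability), `vcov_delta`,
#'   `gamma` (3 x v category coefficients, reference row zero), `fitted`
#'   (per-individual `p1`, `p2`, `c0`), `logLik`, `df`, `n`, and the design.
#' @seealso [never_captured_probability()], [horvitz_thompson()]
#' @examples
#' d <- data.frame(w1 = c(1, 0, 1, 1, 0, 1), w2 = c(0, 1, 1, 1, 1, 0),
#'                 weight = c(0.8, 1.1, 1.3, 0.9, 1.0, 1.2))
#' fit <- fit_capture(~weight, d)
#' coef(fit)
#' @export
fit_capture <- function(x, ...) UseMethod("fit_capture")

#' @rdname fit_capture
#' @export
fit_capture.formula <- function(x, data, ...) {
  tm <- stats::terms(x, data = data)
  covs <- attr(tm, "term.labels")
  fit_capture(build_capture_design(data, covs,
                                   intercept = attr(tm, "intercept") == 1), ...)
}

#' @rdname fit_capture
#' @export
fit_capture.capture_design <- function(x, method = c("multinomial", "poisson"),
                                       ref = 1L, bayes = FALSE, prior_sd = 10,
                                       tol_grad = 1e-8, tol_loglik = 1e-10,
                                       max_iter = 500L, ...) {
  method <- match.arg(method)
  counts <- colSums(x$y)
  if (any(counts == 0)) {
    empty <- which(counts == 0)[1L]
    stop("estimation is degenerate: no individuals in capture category ",
         empty, " (", c("(1,0)", "(0,1)", "(1,1)")[empty], ")", call. = FALSE)
  }
  n <- nrow(x$z)
  v <- ncol(x$z)
  if (n < v + 1) stop("need more individuals than coefficients", call. = FALSE)
  if (method == "poisson") {
    fit <- fit_capture_poisson(x)
  } else {
    if (!ref %in% 1:3) stop("`ref` must be 1, 2 or 3", call. = FALSE)
    fit <- fit_capture_newton(x, as.integer(ref), bayes, prior_sd,
                              tol_grad, tol_loglik, max_iter)
  }
  fit$method <- method
  fit$call <- match.call()
  z <- x$z
  p1 <- stats::plogis(drop(z %*% fit$delta[, 1L]))
  p2 <- stats::plogis(drop(z %*% fit$delta[, 2L]))
  fit$fitted <- data.frame(p1 = p1, p2 = p2, c0 = (1 - p1) * (1 - p2))
  fit$design <- x
  fit$n <- n
  class(fit) <- "capture_fit"
  fit
}

# Full gamma matrix (3 x v) from the free parameter vector, reference row zero.
cap_gamma <- function(theta, v, ref) {
  g <- matrix(0, 3, v)
  g[-ref, ] <- matrix(theta, 2, v, byrow = TRUE)
  g
}

# Conditional multinomial negative log likelihood and derivatives.
cap_nll <- function(theta, z, y, ref) {
  g <- cap_gamma(theta, ncol(z), ref)
  V <- z %*% t(g)                       # n x 3 linear predictors
  V <- V - apply(V, 1, max)
  lse <- log(rowSums(exp(V)))
  -sum(rowSums(y * V) - lse)
}

cap_probs <- function(theta, z, ref) {
  g <- cap_gamma(theta, ncol(z), ref)
  V <- z %*% t(g)
  V <- V - apply(V, 1, max)
  eV <- exp(V)
  eV / rowSums(eV)
}

fit_capture_newton <- function(design, ref, bayes, prior_sd,
                               tol_grad, tol_loglik, max_iter) {
  z <- design$z
  y <- design$y
  v <- ncol(z)
  free <- setdiff(1:3, ref)
  theta <- rep(0, 2 * v)
  pen <- if (bayes) 1 / prior_sd^2 else 0
  nll_pen <- function(th) cap_nll(th, z, y, ref) + 0.5 * pen * sum(th^2)
  f <- nll_pen(theta)
  trace <- data.frame(iter = integer(), nll = numeric(), grad_norm = numeric())
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi <- cap_probs(theta, z, ref)
    # gradient and Hessian of the penalised negative log likelihood
    grad <- numeric(2 * v)
    H <- matrix(0, 2 * v, 2 * v)
    for (a in 1:2) {
      ka <- free[a]
      grad[((a - 1) * v + 1):(a * v)] <- -crossprod(z, y[, ka] - pi[, ka])
      for (b in a:2) {
        kb <- free[b]
        w <- pi[, ka] * ((ka == kb) - pi[, kb])
        blk <- crossprod(z * w, z)
        H[((a - 1) * v + 1):(a * v), ((b - 1) * v + 1):(b * v)] <- blk
        if (b > a) H[((b - 1) * v + 1):(b * v), ((a - 1) * v + 1):(a * v)] <- t(blk)
      }
    }
    grad <- grad + pen * theta
    diag(H) <- diag(H) + pen
    gn <- sqrt(sum(grad^2))
    trace <- rbind(trace, data.frame(iter = it, nll = f, grad_norm = gn))
    if (gn < tol_grad) { converged <- TRUE; break }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop_nonconv("Hessian is singular (possible covariate collinearity or separation)",
                   trace)
    }
    # damped Newton: halve until the objective decreases
    lam <- 1
    repeat {
      f_new <- nll_pen(theta - lam * step)
      if (is.finite(f_new) && f_new <= f) break
      lam <- lam / 2
      if (lam < 1e-10) stop_nonconv("step halving failed to decrease the objective", trace)
    }
    theta <- theta - lam * step
    if (abs(f - f_new) < tol_loglik * (abs(f) + 1e-10)) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
    if (max(abs(theta)) > 100) {
      stop_nonconv("coefficients diverging: categories appear perfectly separated",
                   trace)
    }
  }
  if (!converged) stop_nonconv("Newton iteration limit reached", trace)
  pi <- cap_probs(theta, z, ref)
  H <- cap_hessian(theta, z, pi, free, pen)
  vcov_theta <- tryCatch(solve(H), error = function(e)
    stop_nonconv("observed information is singular at the optimum", trace))
  if (any(diag(vcov_theta) > 1e6)) {
    stop_nonconv(paste0("effectively infinite standard errors at the optimum; ",
                        "some categories appear perfectly separated"), trace)
  }
  g <- cap_gamma(theta, v, ref)
  # delta1 = gamma3 - gamma2 (session 1), delta2 = gamma3 - gamma1 (session 2)
  L <- delta_transform(v, ref)
  delta <- matrix(L %*% theta, v, 2,
                  dimnames = list(colnames(z), c("delta1", "delta2")))
  vcov_delta <- L %*% vcov_theta %*% t(L)
  nm <- c(paste0("delta1.", colnames(z)), paste0("delta2.", colnames(z)))
  dimnames(vcov_delta) <- list(nm, nm)
  ll <- -cap_nll(theta, z, design$y, ref)
  list(gamma = g, theta = theta, vcov_theta = vcov_theta,
       delta = delta, vcov_delta = vcov_delta,
       logLik = ll, df = 2L * v, ref = ref, bayes = bayes,
       prior_sd = if (bayes) prior_sd else NULL,
       iterations = nrow(trace), trace = trace)
}

cap_hessian <- function(theta, z, pi, free, pen) {
  v <- ncol(z)
  H <- matrix(0, 2 * v, 2 * v)
  for (a in 1:2) {
    for (b in a:2) {
      w <- pi[, free[a]] * ((free[a] == free[b]) - pi[, free[b]])
      blk <- crossprod(z * w, z)
      H[((a - 1) * v + 1):(a * v), ((b - 1) * v + 1):(b * v)] <- blk
      if (b > a) H[((b - 1) * v + 1):(b * v), ((a - 1) * v + 1):(a * v)] <- t(blk)
    }
  }
  diag(H) <- diag(H) + pen
  H
}

# Linear map from the stacked free coefficients (gamma_a, gamma_b), a < b the
# non-reference categories, to the differences (gamma3 - gamma2, gamma3 - gamma1).
delta_transform <- function(v, ref) {
  I <- diag(v)
  Z <- matrix(0, v, v)
  blocks <- switch(ref,
    `1` = list(rbind(cbind(-I, I), cbind(Z, I))),   # free = (g2, g3)
    `2` = list(rbind(cbind(Z, I), cbind(-I, I))),   # free = (g1, g3)
    `3` = list(rbind(cbind(Z, -I), cbind(-I, Z))))  # free = (g1, g2)
  blocks[[1L]]
}

stop_nonconv <- function(msg, trace) {
  cond <- structure(
    class = c("capdyn_nonconvergence", "error", "condition"),
    list(message = paste0("capture-model fit did not converge: ", msg),
         call = NULL, trace = trace))
  stop(cond)
}

fit_capture_poisson <- function(design) {
  aug <- expand_to_poisson(design)
  covcols <- setdiff(names(aug), c("id", "cat", "y"))
  fml <- stats::as.formula(paste(
    "y ~ 0 + id +", paste(sprintf("`%s`", covcols), collapse = " + ")))
  gfit <- stats::glm(fml, family = stats::poisson(), data = aug)
  cf <- stats::coef(gfit)
  names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
  v <- ncol(design$z)
  nm2 <- paste0(colnames(design$z), ".cat2")
  nm3 <- paste0(colnames(design$z), ".cat3")
  theta <- c(cf[nm2], cf[nm3])          # reference category 1
  Vfull <- stats::vcov(gfit)
  dimnames(Vfull) <- lapply(dimnames(Vfull), gsub,
                            pattern = "`", replacement = "", fixed = TRUE)
  Vfull <- Vfull[c(nm2, nm3), c(nm2, nm3)]
  L <- delta_transform(v, 1L)
  delta <- matrix(L %*% theta, v, 2,
                  dimnames = list(colnames(design$z), c("delta1", "delta2")))
  vcov_delta <- L %*% Vfull %*% t(L)
  nm <- c(paste0("delta1.", colnames(design$z)), paste0("delta2.", colnames(design$z)))
  dimnames(vcov_delta) <- list(nm, nm)
  ll <- -cap_nll(theta, design$z, design$y, 1L)
  list(gamma = cap_gamma(theta, v, 1L), theta = theta, vcov_theta = Vfull,
       delta = delta, vcov_delta = vcov_delta,
       logLik = ll, df = 2L * v, ref = 1L, bayes = FALSE,
       beta = cf[grep("^id", names(cf))],
       iterations = gfit$iter, trace = NULL)
}

#' Never-capture probability of each captured individual
#'
#' Returns the fitted probability that each captured individual would have
#' been missed on both sessions, `c0 = (1 - p1)(1 - p2)`. These are the
#' inverse-weight ingredients of the Horvitz-Thompson abundance estimator.
#'
#' @param fit A `"capture_fit"`.
#' @return Numeric vector in (0, 1), one element per captured individual.
#' @export
never_captured_probability <- function(fit) {
  stopifnot(inherits(fit, "capture_fit"))
  fit$fitted$c0
}

#' @export
coef.capture_fit <- function(object, ...) {
  d <- object$delta
  stats::setNames(c(d[, 1L], d[, 2L]),
                  c(paste0("delta1.", rownames(d)), paste0("delta2.", rownames(d))))
}

#' @export
vcov.capture_fit <- function(object, ...) object$vcov_delta

#' @export
logLik.capture_fit <- function(object, ...) {
  if (isTRUE(object$bayes)) {
    stop("the Bayesian-mode fit maximises a penalised objective; ",
         "a maximised likelihood is not available", call. = FALSE)
  }
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
nobs.capture_fit <- function(object, ...) object$n

#' Predict session capture probabilities for new individuals
#'
#' @param object A `"capture_fit"`.
#' @param newdata Optional data frame with the covariate columns of the fit;
#'   defaults to the fitted individuals.
#' @param ... Unused.
#' @return Data frame with columns `p1`, `p2`, `c0`.
#' @export
predict.capture_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  z <- build_newdata_matrix(object$design, newdata)
  p1 <- stats::plogis(drop(z %*% object$delta[, 1L]))
  p2 <- stats::plogis(drop(z %*% object$delta[, 2L]))
  data.frame(p1 = p1, p2 = p2, c0 = (1 - p1) * (1 - p2))
}

build_newdata_matrix <- function(design, newdata) {
  cols <- colnames(design$z)
  n <- nrow(newdata)
  z <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (j in cols) {
    if (j == "(Intercept)") { z[, j] <- 1; next }
    if (j %in% names(newdata)) { z[, j] <- as.numeric(newdata[[j]]); next }
    # indicator column of a categorical covariate: "<name><level>"
    base <- Filter(function(nm) startsWith(j, nm), names(newdata))
    if (!length(base)) stop("newdata lacks a column for design term `", j, "`",
                            call. = FALSE)
    base <- base[which.max(nchar(base))]
    lev <- substring(j, nchar(base) + 1L)
    z[, j] <- as.numeric(as.character(newdata[[base]]) == lev)
  }
  z
}

#' @export
fitted.capture_fit <- function(object, ...) object$fitted

#' @export
print.capture_fit <- function(x, digits = 4, ...) {
  cat("Two-session Mth capture model (conditional multinomial likelihood)\n")
  cat("  individuals:", x$n, " method:", x$method,
      if (isTRUE(x$bayes)) " [Gaussian posterior approximation]" else "", "\n")
  cat("Coefficient differences:\n")
  print(round(x$delta, digits))
  if (!isTRUE(x$bayes)) {
    cat(sprintf("logLik: %.*f   AIC: %.*f   BIC: %.*f\n",
                digits, x$logLik, digits, stats::AIC(x), digits, stats::BIC(x)))
  }
  invisible(x)
}

#' @export
summary.capture_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_delta))
  est <- coef(object)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `z value` = est / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(est / se)))
  out <- list(coefficients = tab, n = object$n, logLik = object$logLik,
              bayes = isTRUE(object$bayes), method = object$method,
              df = object$df,
              fitted_summary = vapply(object$fitted, stats::quantile, numeric(5),
                                      probs = c(0, .25, .5, .75, 1)))
  class(out) <- "summary.capture_fit"
  out
}

#' @export
print.summary.capture_fit <- function(x, digits = 4, ...) {
  cat("Two-session Mth capture model,", x$n, "captured individuals\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nFitted probability summary (rows: min/quartiles/max):\n")
  print(round(x$fitted_summary, digits))
  if (!x$bayes) {
    cat(sprintf("\nlogLik %.3f on %d coefficients\n", x$logLik, x$df))
  }
  invisible(x)
}
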