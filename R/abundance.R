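#' Horvitz-Thompson abundance estimate
#'
#' Sums the inverse inclusion probabilities of the captured individuals:
#' `N_hat = sum_i 1 / (1 - c0_i)`, where `c0_i` is the probability that
#' individual i is never captured. The estimate always dominates the observed
#' count, with equality exactly when every `c0_i` is zero.
#'
#' @param c0 Numeric vector of never-capture probabilities in `[0, 1)`, one
#'   per captured individual (see [never_captured_probability()]).
#' @return The abundance estimate, a single number `>= length(c0)`.
#' @examples
#' horvitz_thompson(rep(0.1125, 100))  # ~112.7
#' @export
horvitz_thompson <- function(c0) {
  if (!is.numeric(c0) || any(c0 < 0 | c0 >= 1)) {
    stop("never-capture probabilities must lie in [0, 1)", call. = FALSE)
  }
  sum(1 / (1 - c0))
}

#' Per-time-point Horvitz-Thompson abundance series
#'
#' Groups the captured individuals of a fitted capture model by time point
#' (and site) and computes the Horvitz-Thompson abundance estimate at each,
#' using each individual's own fitted never-capture probability. Time points
#' inside the observed range with zero captures are reported as missing
#' (`NA`), never as zero: the log abundance is undefined there and downstream
#' series fitting must decide how to split.
#'
#' @param data Data frame of captured individuals with integer column `time`
#'   (1-based within a series) and optionally `site`; must be the rows the
#'   capture model was fitted to, in the same order.
#' @param fit The `"capture_fit"` for those individuals.
#' @param time_points Optional integer vector of time points the series should
#'   cover; defaults to `1:max(data$time)`.
#' @return An object of class `"abundance_series"`: a data frame with columns
#'   `site`, `time`, `n` (observed captures), `N_hat`, `log_N_hat`.
#' @export
abundance_series <- function(data, fit, time_points = NULL) {
  stopifnot(inherits(fit, "capture_fit"))
  if (!"time" %in% names(data)) stop("`data` needs a `time` column", call. = FALSE)
  if (nrow(data) != fit$n) {
    stop("`data` must contain exactly the individuals the model was fitted to",
         call. = FALSE)
  }
  site <- if ("site" %in% names(data)) as.character(data$site[1]) else "site1"
  if (is.null(time_points)) time_points <- seq_len(max(data$time))
  c0 <- never_captured_probability(fit)
  wts <- 1 / (1 - c0)
  f <- factor(data$time, levels = time_points)
  n_t <- as.integer(table(f))
  N_hat <- as.numeric(tapply(wts, f, sum))
  N_hat[n_t == 0L] <- NA_real_
  out <- data.frame(site = site, time = time_points, n = n_t,
                    N_hat = N_hat, log_N_hat = log(N_hat))
  if (any(n_t == 0L)) {
    attr(out, "missing_times") <- time_points[n_t == 0L]
  }
  class(out) <- c("abundance_series", "data.frame")
  out
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("Horvitz-Thompson abundance series, site", x$site[1],
      "-", nrow(x), "time points\n")
  print.data.frame(x, row.names = FALSE)
  mt <- attr(x, "missing_times")
  if (length(mt)) cat("zero-capture time points marked missing:",
                      paste(mt, collapse = ", "), "\n")
  invisible(x)
}
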