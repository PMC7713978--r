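# Delimited-text interchange formats. Capture tables are CSV with a mandatory
# header `id,site,time,w1,w2,<covariate...>`; abundance series are CSV
# `site,series,time,n,N_hat,log_N_hat`. Comma separator, '.' decimal point,
# UTF-8 - matching common ecology field-data conventions and keeping fixtures
# diffable.

#' Read a capture-history table
#'
#' @param path CSV file with header columns `id,site,time,w1,w2` plus any
#'   covariates. `w1`/`w2` must be 0 or 1; `time` a positive integer.
#' @param allow_uncaptured If `FALSE` (the default for fitting inputs), rows
#'   with history (0,0) are rejected; truth sidecar tables may set `TRUE`.
#' @return Data frame of typed records; character covariates keep their file
#'   order of first appearance as factor levels, so treatment coding is
#'   reproducible.
#' @export
read_capture_table <- function(path, allow_uncaptured = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "site", "time", "w1", "w2")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("capture table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("w1", "w2")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad)) {
      stop("invalid ", col, " value '", df[[col]][bad[1]], "' at line ",
           bad[1] + 1L, " of ", path, " (must be 0 or 1)", call. = FALSE)
    }
    df[[col]] <- as.integer(df[[col]])
  }
  tnum <- suppressWarnings(as.numeric(df$time))
  bad <- which(is.na(tnum) | tnum < 1 | tnum != floor(tnum))
  if (length(bad)) {
    stop("invalid time value '", df$time[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path, " (must be a positive integer)", call. = FALSE)
  }
  df$time <- as.integer(tnum)
  if (!allow_uncaptured) {
    bad <- which(df$w1 == 0L & df$w2 == 0L)
    if (length(bad)) {
      stop("capture history (0,0) at line ", bad[1] + 1L, " of ", path,
           "; never-captured rows cannot enter a conditional fit", call. = FALSE)
    }
  }
  covs <- setdiff(names(df), required)
  for (cv in covs) {
    if (is.character(df[[cv]])) {
      df[[cv]] <- factor(df[[cv]], levels = unique(df[[cv]]))
    }
  }
  df
}

#' Write a capture-history table
#'
#' @param data Data frame with at least `id,site,time,w1,w2`.
#' @param path Output CSV path.
#' @export
write_capture_table <- function(data, path) {
  required <- c("id", "site", "time", "w1", "w2")
  miss <- setdiff(required, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ord <- c(required, setdiff(names(data), required))
  utils::write.csv(data[ord], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an abundance series table
#'
#' @param series An `"abundance_series"` (or compatible data frame).
#' @param path Output CSV path.
#' @param series_label Label for the `series` column (e.g. a season).
#' @export
write_abundance_series <- function(series, path, series_label = "series1") {
  out <- data.frame(site = series$site, series = series_label,
                    time = series$time, n = series$n,
                    N_hat = series$N_hat, log_N_hat = series$log_N_hat)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an abundance series table
#'
#' @param path CSV written by [write_abundance_series()].
#' @return Data frame with columns `site,series,time,n,N_hat,log_N_hat`.
#' @export
read_abundance_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "series", "time", "n", "N_hat", "log_N_hat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("series table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Export a capture fit report
#'
#' Writes the coefficient differences, their standard errors, and the
#' information criteria as JSON.
#'
#' @param fit A `"capture_fit"`.
#' @param path Output path.
#' @export
write_capture_report <- function(fit, path) {
  stopifnot(inherits(fit, "capture_fit"))
  rep <- list(
    n = fit$n,
    method = fit$method,
    delta = as.list(coef(fit)),
    se = as.list(stats::setNames(sqrt(diag(fit$vcov_delta)),
                                 names(coef(fit)))))
  if (!isTRUE(fit$bayes)) {
    rep$logLik <- fit$logLik
    rep$AIC <- stats::AIC(fit)
    rep$BIC <- stats::BIC(fit)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
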