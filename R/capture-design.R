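#' Build the multinomial design for a two-session capture-recapture fit
#'
#' Arranges captured individuals for conditional multinomial-likelihood
#' estimation: a one-hot response matrix over the three observable capture
#' categories (1 = caught session 1 only, 2 = session 2 only, 3 = both) and a
#' covariate matrix. Categorical covariates are expanded to treatment-coded
#' indicator columns with the alphabetically first level as baseline, so the
#' coding is reproducible across files with the same level sets.
#'
#' @param data Data frame of captured individuals containing binary columns
#'   `w1` and `w2` plus the covariates named in `covariates`.
#' @param covariates Character vector of covariate column names (the linear
#'   predictor is built from these, in this order).
#' @param intercept Logical; prepend a column of ones. The simulator's weight-
#'   only model uses `intercept = FALSE`.
#' @return An object of class `"capture_design"`: a list with the response
#'   matrix `y` (n x 3), covariate matrix `z` (n x v), category codes `k`,
#'   and the originating data.
#' @export
build_capture_design <- function(data, covariates = character(), intercept = TRUE) {
  if (!all(c("w1", "w2") %in% names(data))) {
    stop("`data` must contain binary capture columns `w1` and `w2`", call. = FALSE)
  }
  k <- capture_category(data$w1, data$w2)
  if (any(k == 0L)) {
    stop("records with capture history (0,0) cannot enter the conditional fit",
         call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  cols <- if (intercept) list(`(Intercept)` = rep(1, n)) else list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (anyNA(x)) {
      stop("covariate `", cv, "` has missing values on captured rows", call. = FALSE)
    }
    if (is.numeric(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1]) {  # treatment coding, first level alphabetically is baseline
        cols[[paste0(cv, l)]] <- as.numeric(as.character(x) == l)
      }
    }
  }
  if (!length(cols)) {
    stop("design needs at least one column: give covariates or an intercept",
         call. = FALSE)
  }
  z <- do.call(cbind, cols)
  colnames(z) <- names(cols)
  y <- matrix(0, n, 3, dimnames = list(NULL, c("cat1", "cat2", "cat3")))
  y[cbind(seq_len(n), k)] <- 1
  structure(list(y = y, z = z, k = k, data = data),
            class = "capture_design")
}

#' @export
print.capture_design <- function(x, ...) {
  cat("Capture-recapture multinomial design\n")
  cat("  individuals:", nrow(x$z), "\n")
  cat("  columns:", paste(colnames(x$z), collapse = ", "), "\n")
  cat("  category counts (1,0)/(0,1)/(1,1):",
      paste(colSums(x$y), collapse = " / "), "\n")
  invisible(x)
}

#' Expand a capture design via the multinomial-Poisson transformation
#'
#' Re-expresses the three-category multinomial response as independent Poisson
#' counts: each individual contributes one row per observable category with a
#' 0/1 count, category-specific copies of every covariate column, and an
#' individual identifier whose per-individual intercept plays the role of the
#' auxiliary nuisance parameter of the transformation. Fitting a log-link
#' Poisson model with those per-individual intercepts maximises a likelihood
#' proportional to the conditional multinomial likelihood, so the
#' category-coefficient estimates agree with the direct multinomial fit.
#'
#' @param design A `"capture_design"`.
#' @return A data frame with `3 * n` rows and columns `id` (factor), `cat`
#'   (factor with levels 1:3), `y` (0/1 count), and one column
#'   `<col>.cat2`, `<col>.cat3` per design column (category 1 is the
#'   reference, its copies are identically zero and omitted).
#' @export
expand_to_poisson <- function(design) {
  stopifnot(inherits(design, "capture_design"))
  n <- nrow(design$z)
  v <- ncol(design$z)
  id <- factor(rep(seq_len(n), each = 3))
  cat <- factor(rep(1:3, n))
  y <- as.integer(t(design$y))
  out <- data.frame(id = id, cat = cat, y = y)
  for (j in seq_len(v)) {
    zj <- rep(design$z[, j], each = 3)
    out[[paste0(colnames(design$z)[j], ".cat2")]] <- zj * (cat == "2")
    out[[paste0(colnames(design$z)[j], ".cat3")]] <- zj * (cat == "3")
  }
  out
}
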