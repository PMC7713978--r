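#' Capture-history category probabilities for two sessions
#'
#' For a closed population sampled on two occasions with independent session
#' capture probabilities `p1` and `p2` (the Mth heterogeneity model), the four
#' possible capture histories define categories 0 to 3: 0 = (0,0) never
#' captured, 1 = (1,0), 2 = (0,1), 3 = (1,1). This function returns the
#' unconditional probability of each category together with the probabilities
#' of the three observable categories conditional on being captured at least
#' once.
#'
#' @param p1,p2 Numeric vectors of session capture probabilities, strictly
#'   inside (0, 1). Recycled to a common length.
#' @return A data frame of class `"category_probs"` with columns `p1`, `p2`,
#'   `c0`, `c1`, `c2`, `c3` (unconditional category probabilities, summing to
#'   1) and `c_tilde1`, `c_tilde2`, `c_tilde3` (probabilities conditional on
#'   capture, summing to 1).
#' @examples
#' category_probabilities(0.55, 0.75)
#' @export
category_probabilities <- function(p1, p2) {
  if (!is.numeric(p1) || !is.numeric(p2)) {
    stop("`p1` and `p2` must be numeric", call. = FALSE)
  }
  n <- max(length(p1), length(p2))
  p1 <- rep_len(p1, n)
  p2 <- rep_len(p2, n)
  if (any(p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1)) {
    stop("capture probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  c0 <- (1 - p1) * (1 - p2)
  c1 <- p1 * (1 - p2)
  c2 <- (1 - p1) * p2
  c3 <- p1 * p2
  cap <- 1 - c0
  out <- data.frame(
    p1 = p1, p2 = p2,
    c0 = c0, c1 = c1, c2 = c2, c3 = c3,
    c_tilde1 = c1 / cap, c_tilde2 = c2 / cap, c_tilde3 = c3 / cap
  )
  class(out) <- c("category_probs", "data.frame")
  out
}

#' Map two-session capture indicators to category codes
#'
#' @param w1,w2 Binary (0/1) capture indicators for sessions 1 and 2.
#' @return Integer category codes: 0 for (0,0), 1 for (1,0), 2 for (0,1),
#'   3 for (1,1).
#' @export
capture_category <- function(w1, w2) {
  if (length(w1) != length(w2)) {
    stop("`w1` and `w2` must have the same length", call. = FALSE)
  }
  if (!all(w1 %in% c(0, 1)) || !all(w2 %in% c(0, 1))) {
    stop("`w1` and `w2` must be binary 0/1 indicators", call. = FALSE)
  }
  as.integer(w1 + 2L * w2)
}
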