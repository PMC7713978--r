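# Fixtures built in code: capture tables with known generative parameters.

# Captured-individual table from the Mth model with weight the sole covariate
# (no intercept), delta1 = logit(p1), delta2 = logit(p2) at weight 1.
make_capture_data <- function(n, seed, p1 = 0.55, p2 = 0.75, sd_log_w = 0.3) {
  set.seed(seed)
  z <- rlnorm(n, 0, sd_log_w)
  pr1 <- plogis(qlogis(p1) * z)
  pr2 <- plogis(qlogis(p2) * z)
  w1 <- rbinom(n, 1, pr1)
  w2 <- rbinom(n, 1, pr2)
  keep <- (w1 + w2) > 0
  data.frame(weight = z[keep], w1 = w1[keep], w2 = w2[keep])
}

# Intercept-only table with fixed category counts: n1 of (1,0), n2 of (0,1),
# n3 of (1,1).
counts_to_data <- function(n1, n2, n3) {
  data.frame(w1 = c(rep(1L, n1), rep(0L, n2), rep(1L, n3)),
             w2 = c(rep(0L, n1), rep(1L, n2), rep(1L, n3)))
}

# Full records table (id/site/time columns) for io and abundance tests.
make_records <- function(n, seed, T = 4) {
  d <- make_capture_data(n, seed)
  d$id <- sprintf("i%04d", seq_len(nrow(d)))
  d$site <- "siteA"
  d$time <- rep_len(seq_len(T), nrow(d))
  d[order(d$time), c("id", "site", "time", "w1", "w2", "weight")]
}
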