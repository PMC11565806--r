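# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_probe <- function() {
  if (is.null(.fixtures$probe)) .fixtures$probe <- generate_probe()
  .fixtures$probe
}

fixture_config <- function() {
  if (is.null(.fixtures$config)) .fixtures$config <- sim_config(seed = 1)
  .fixtures$config
}

fixture_cohort <- function(n = 20) {
  key <- paste0("cohort", n)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- participant_metrics(
      generate_participants(n, fixture_config(), seed = 123))
  }
  .fixtures[[key]]
}

# Two-wavelength recording with fully specified traces, for metric
# oracles: `traces` is a list of time x 2 matrices, one per channel.
manual_recording <- function(traces, fs = 10.2, power = NULL,
                             rois = NULL) {
  n_ch <- length(traces)
  n_time <- nrow(traces[[1]])
  data <- array(0, dim = c(n_time, n_ch, 2))
  for (i in seq_len(n_ch)) data[, i, ] <- traces[[i]]
  channels <- tibble::tibble(
    channel = seq_len(n_ch),
    roi = if (is.null(rois)) rep("side", n_ch) else rois,
    hemisphere = "right", kind = "long", separation_mm = 30)
  new_recording(data, fs, channels = channels, source_power_pct = power)
}

# Brute-force zero-lag normalised cross-correlation by direct summation
# (independent of stats::cor).
direct_zero_lag_corr <- function(a, b) {
  a <- a - sum(a) / length(a)
  b <- b - sum(b) / length(b)
  num <- 0
  da <- 0
  db <- 0
  for (k in seq_along(a)) {
    num <- num + a[k] * b[k]
    da <- da + a[k]^2
    db <- db + b[k]^2
  }
  num / sqrt(da * db)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (no ties assumed).
permutation_mw_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, u_of)
  mu <- n1 * length(g2) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
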