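#' Construct an intensity recording from components
#'
#' Builds an `fnirs_recording` from a raw data array and validates the
#' invariants: positive sampling rate, source-power percentages in
#' (0, 100], and a channel table covering the data's channel dimension.
#' Mostly useful for constructing controlled inputs in analyses and
#' tests; simulated recordings come from [generate_recording()].
#'
#' @param data Array time x channel x wavelength (a time x channel
#'   matrix is promoted to one wavelength).
#' @param fs Sampling rate (Hz).
#' @param channels Channel tibble (`channel`, `roi`, `hemisphere`,
#'   `kind`, `separation_mm`; missing columns are filled with defaults).
#' @param source_power_pct Channel x wavelength matrix (default 100).
#' @param wavelengths Wavelengths in nm.
#' @param run_label,participant_id Metadata labels.
#' @return An `fnirs_recording`.
#' @export
new_recording <- function(data, fs, channels = NULL,
                          source_power_pct = NULL,
                          wavelengths = c(760, 850),
                          run_label = "rest_proper_cap",
                          participant_id = NA_character_) {
  if (length(dim(data)) == 2) {
    data <- array(data, dim = c(dim(data), 1))
  }
  if (fs <= 0) stop("fs must be positive")
  n_ch <- dim(data)[2]
  n_wl <- dim(data)[3]
  if (is.null(channels)) {
    channels <- tibble::tibble(channel = seq_len(n_ch), roi = "side",
                               hemisphere = "right", kind = "long",
                               separation_mm = 30)
  }
  for (col in c("roi", "hemisphere", "kind", "separation_mm")) {
    if (!col %in% names(channels)) {
      channels[[col]] <- switch(col, roi = "side", hemisphere = "right",
                                kind = "long", separation_mm = 30)
    }
  }
  if (nrow(channels) != n_ch) stop("channel table does not match data")
  if (is.null(source_power_pct)) {
    source_power_pct <- matrix(100, n_ch, n_wl)
  }
  if (any(source_power_pct <= 0 | source_power_pct > 100)) {
    stop("source power percentages must lie in (0, 100]")
  }
  structure(list(data = data, fs = fs, wavelengths = wavelengths,
                 channels = channels,
                 source_power_pct = source_power_pct,
                 run_label = run_label, participant_id = participant_id),
            class = "fnirs_recording")
}

channel_index <- function(rec, channel) {
  i <- match(channel, rec$channels$channel)
  if (is.na(i)) stop("unknown channel id: ", channel)
  i
}

#' Uncorrected signal mean
#'
#' Mean of the raw intensity time course, averaged across the two
#' wavelengths. Used in the NEP analysis and the capping comparison.
#'
#' @param rec An `fnirs_recording`.
#' @param channel Channel id (from `rec$channels$channel`).
#' @return Raw-unit mean.
#' @export
uncorrected_signal_mean <- function(rec, channel) {
  i <- channel_index(rec, channel)
  if (dim(rec$data)[1] < 1) stop("empty trace")
  mean(colMeans(rec$data[, i, , drop = TRUE]))
}

#' Corrected signal mean
#'
#' Source-power-corrected, log-transformed signal mean: per wavelength the
#' raw mean is divided by the LED source-power percentage and multiplied
#' by 100; the two corrected means are averaged and then log10
#' transformed (`order = "average-then-log"`, the default) or
#' log-transformed per wavelength and then averaged
#' (`order = "log-then-average"`). A non-positive mean makes the value
#' undefined; it is returned as `NA` with a warning rather than dropped
#' silently.
#'
#' @inheritParams uncorrected_signal_mean
#' @param order Wavelength-averaging order (see Details).
#' @return log10-unit corrected mean.
#' @examples
#' # mean 0.5 at 50% power: log10(0.5 / 50 * 100) = 0
#' @export
corrected_signal_mean <- function(rec, channel,
                                  order = c("average-then-log",
                                            "log-then-average")) {
  order <- match.arg(order)
  i <- channel_index(rec, channel)
  pw <- rec$source_power_pct[i, ]
  if (any(pw <= 0)) stop("source power percentage must be positive")
  m <- colMeans(rec$data[, i, , drop = TRUE])
  if (any(m <= 0)) {
    warning("non-positive mean intensity in channel ", channel,
            "; corrected signal mean undefined")
    return(NA_real_)
  }
  corrected <- m / pw * 100
  if (order == "average-then-log") log10(mean(corrected))
  else mean(log10(corrected))
}

#' Scalp coupling index (SCI)
#'
#' Band-pass filters the two wavelength traces to the cardiac band
#' (default 0.5-2.5 Hz, zero-phase third-order Butterworth), normalises
#' each to unit standard deviation and returns their zero-lag
#' cross-correlation (the Pearson correlation at lag 0). Values near 1
#' indicate that both wavelengths carry the same pulsatile waveform,
#' i.e. good optode-scalp coupling.
#'
#' @inheritParams uncorrected_signal_mean
#' @param band Pass band in Hz.
#' @param order Butterworth design order (applied forward-backward).
#' @return SCI in \[-1, 1\]; `NA` with a warning if a filtered trace has
#'   zero variance.
#' @export
scalp_coupling_index <- function(rec, channel, band = c(0.5, 2.5),
                                 order = 3) {
  i <- channel_index(rec, channel)
  if (dim(rec$data)[1] < 10 * rec$fs) {
    stop("SCI requires at least 10 s of samples")
  }
  bf <- signal::butter(order, band / (rec$fs / 2), type = "pass")
  # Remove the DC level first: the band-pass would otherwise ring at the
  # trace edges with an amplitude set by the baseline, not the cardiac
  # signal, and that shared transient biases the correlation upwards.
  x1 <- rec$data[, i, 1]
  x2 <- rec$data[, i, 2]
  f1 <- signal::filtfilt(bf, x1 - mean(x1))
  f2 <- signal::filtfilt(bf, x2 - mean(x2))
  if (sd(f1) == 0 || sd(f2) == 0) {
    warning("zero-variance filtered trace in channel ", channel,
            "; SCI undefined")
    return(NA_real_)
  }
  cor(f1 / sd(f1), f2 / sd(f2))
}

#' Fisher z-transformation
#'
#' `z = atanh(r)`, with `|r|` clipped at `1 - 1e-12` so degenerate
#' perfect correlations stay finite.
#'
#' @param r Correlations.
#' @return z values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

# SNR of a time x wavelength raw-intensity matrix: mean/SD per
# wavelength, averaged across wavelengths; a constant trace counts as
# infinitely clean.
channel_snr <- function(trace) {
  if (is.null(dim(trace))) trace <- matrix(trace, ncol = 1)
  if (nrow(trace) < 2) stop("SNR requires at least two samples")
  s <- apply(trace, 2, sd)
  m <- colMeans(trace)
  ratio <- ifelse(s == 0, Inf, m / s)
  mean(ratio)
}

#' Raw-intensity signal-to-noise ratio of a channel
#'
#' `mean / SD` of the unfiltered intensity per wavelength, averaged
#' across the two wavelengths. A zero-SD (noiseless) trace yields `Inf`
#' and is never pruned.
#'
#' @inheritParams uncorrected_signal_mean
#' @return Unitless SNR.
#' @export
snr <- function(rec, channel) {
  i <- channel_index(rec, channel)
  channel_snr(rec$data[, i, ])
}

#' Prune channels below an SNR threshold
#'
#' Retains channels with `snr >= threshold`; a channel strictly below is
#' excluded (so an SNR of exactly 5 is retained at the default).
#'
#' @param qualities A channel-quality tibble (see [channel_quality()]).
#' @param threshold Default 5.
#' @return The retained rows.
#' @export
prune_by_snr <- function(qualities, threshold = 5) {
  qualities[qualities$snr >= threshold, ]
}

#' Channel-level quality table for a recording
#'
#' Computes the uncorrected and corrected signal means, the scalp
#' coupling index with its Fisher z transform, and the raw SNR for every
#' channel.
#'
#' @param rec An `fnirs_recording`.
#' @param snr_threshold Threshold stored in the `pass_snr` flag.
#' @param sci Compute the scalp coupling index (default `TRUE`; skipping
#'   it avoids the band-pass filtering when only the mean-based metrics
#'   are needed, e.g. in large replicate studies).
#' @return A tibble: `participant`, `channel`, `roi`, `hemisphere`,
#'   `kind`, `usm`, `csm`, `sci`, `sci_z`, `snr`, `pass_snr`.
#' @export
channel_quality <- function(rec, snr_threshold = 5, sci = TRUE) {
  ch <- rec$channels
  out <- tibble::tibble(
    participant = rec$participant_id,
    channel = ch$channel, roi = ch$roi, hemisphere = ch$hemisphere,
    kind = ch$kind,
    usm = vapply(ch$channel, function(c)
      uncorrected_signal_mean(rec, c), numeric(1)),
    csm = vapply(ch$channel, function(c)
      corrected_signal_mean(rec, c), numeric(1)),
    sci = if (sci) vapply(ch$channel, function(c)
      scalp_coupling_index(rec, c), numeric(1)) else NA_real_,
    snr = vapply(ch$channel, function(c) snr(rec, c), numeric(1))
  )
  out$sci_z <- fisher_z(out$sci)
  out$pass_snr <- out$snr >= snr_threshold
  out[, c("participant", "channel", "roi", "hemisphere", "kind", "usm",
          "csm", "sci", "sci_z", "snr", "pass_snr")]
}

#' Compare a quality metric between two runs
#'
#' Pools the per-channel values of `metric` in both runs (optionally
#' restricted to one region), reports their means and SDs, the percent
#' increase `100 * (mean2 - mean1) / mean1`, and a two-sided paired
#' t-test on the channel-wise (default) or participant-mean differences.
#' When the paired differences are numerically constant the t statistic
#' is undefined; the comparison then reports p = 1 for a zero difference
#' and p = 0 otherwise.
#'
#' @param run1_qualities,run2_qualities Channel-quality tibbles of the
#'   same channels/participants (run 1 = fast capping, run 2 = proper
#'   capping in the study design).
#' @param metric Column to compare (e.g. `"sci"`, `"usm"`).
#' @param roi Optional region filter.
#' @param by `"channel"` (default; pools channels across participants) or
#'   `"participant"` (averages channels within participant first).
#' @return A one-row tibble: `metric`, `roi`, `n`, `mean1`, `sd1`,
#'   `mean2`, `sd2`, `percent_increase`, `p_paired_t`.
#' @export
compare_runs <- function(run1_qualities, run2_qualities, metric = "sci",
                         roi = NULL, by = c("channel", "participant")) {
  by <- match.arg(by)
  key <- c("participant", "channel")
  q1 <- run1_qualities
  q2 <- run2_qualities
  if (!is.null(roi)) {
    q1 <- q1[q1$roi %in% roi, ]
    q2 <- q2[q2$roi %in% roi, ]
  }
  if (nrow(q1) != nrow(q2)) stop("runs cover different channel sets")
  merged <- dplyr::inner_join(
    q1[, c(key, metric)], q2[, c(key, metric)],
    by = key, suffix = c("_1", "_2"))
  if (nrow(merged) != nrow(q1)) stop("runs cover different channel sets")
  v1 <- merged[[paste0(metric, "_1")]]
  v2 <- merged[[paste0(metric, "_2")]]
  if (by == "participant") {
    agg <- merged %>%
      dplyr::group_by(.data$participant) %>%
      dplyr::summarise(v1 = mean(.data[[paste0(metric, "_1")]]),
                       v2 = mean(.data[[paste0(metric, "_2")]]))
    v1 <- agg$v1
    v2 <- agg$v2
  }
  d <- v2 - v1
  if (sd(d) < 1e-14 * max(1, abs(mean(d)))) {
    p <- if (abs(mean(d)) < 1e-14) 1 else 0
  } else {
    p <- t.test(v2, v1, paired = TRUE)$p.value
  }
  tibble::tibble(
    metric = metric, roi = if (is.null(roi)) "all" else
      paste(roi, collapse = "+"),
    n = length(d),
    mean1 = mean(v1), sd1 = sd(v1), mean2 = mean(v2), sd2 = sd(v2),
    percent_increase = 100 * (mean(v2) - mean(v1)) / mean(v1),
    p_paired_t = p
  )
}
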