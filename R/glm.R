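#' Haemoglobin extinction coefficients at 760 and 850 nm
#'
#' Molar extinction coefficients (1/(cm M)) of oxy- and deoxyhaemoglobin
#' at the two acquisition wavelengths, from the standard Gratzer/Prahl
#' compilation used across fNIRS toolboxes.
#'
#' @return A 2 x 2 matrix, rows named `"760"`/`"850"`, columns
#'   `"hbo"`/`"hbr"`.
#' @export
extinction_coefficients <- function() {
  matrix(c(1486.5865, 3843.707,
           2526.391, 1798.643),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("hbo", "hbr")))
}

#' Modified-gamma HRF specification
#'
#' Parameters of the haemodynamic response kernel per chromophore:
#' `tau` (onset latency, s), `sigma` (width, s) and `duration` (the
#' stimulus boxcar length the kernel is convolved with, s), over the time
#' range -2 to 12 s. The defaults are (0.1, 3, 5) for HbO2 and
#' (1.8, 3, 5) for HbR.
#'
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param tau,sigma,duration Override the defaults.
#' @param range Kernel time range in seconds.
#' @return A list with the four fields.
#' @export
hrf_spec <- function(chromophore = c("hbo", "hbr"), tau = NULL,
                     sigma = 3, duration = 5, range = c(-2, 12)) {
  chromophore <- match.arg(chromophore)
  if (is.null(tau)) tau <- if (chromophore == "hbo") 0.1 else 1.8
  if (sigma <= 0) stop("sigma must be positive")
  if (!(range[1] < 0 && range[2] > 0)) {
    stop("the kernel range must straddle zero")
  }
  list(chromophore = chromophore, tau = tau, sigma = sigma,
       duration = duration, range = range)
}

#' Sampled modified-gamma HRF kernel
#'
#' The kernel is `h(t) = e * u^2 * exp(-u^2)` with `u = (t - tau)/sigma`
#' for `t >= tau` and 0 before, which peaks with value 1 at
#' `t = tau + sigma` (3.1 s for the HbO2 defaults, 4.8 s for HbR).
#'
#' @param spec An [hrf_spec()].
#' @param fs Sampling rate (Hz).
#' @return A tibble with columns `time` (s, spanning `spec$range`) and
#'   `value`.
#' @examples
#' k <- hrf_basis(hrf_spec("hbo"), fs = 10.2)
#' k$time[which.max(k$value)]
#' @export
hrf_basis <- function(spec, fs) {
  t <- seq(spec$range[1], spec$range[2], by = 1 / fs)
  u <- (t - spec$tau) / spec$sigma
  h <- ifelse(t >= spec$tau, exp(1) * u^2 * exp(-u^2), 0)
  tibble::tibble(time = t, value = h)
}

#' Condition regressor: HRF kernel convolved with the stimulus boxcar
#'
#' Convolves the modified-gamma kernel with a boxcar of length
#' `spec$duration` at each of the condition's onsets, then scales so that
#' a single trial peaks at 1. With this scaling a fitted beta is the peak
#' single-trial concentration change in the units of the response series.
#'
#' @param stim An `fnirs_stim`.
#' @param condition Condition name.
#' @param spec An [hrf_spec()].
#' @param fs Sampling rate (Hz).
#' @param n_time Number of samples in the run.
#' @return Numeric regressor of length `n_time`.
#' @export
condition_regressor <- function(stim, condition, spec, fs, n_time) {
  t_pos <- seq(0, spec$range[2], by = 1 / fs)
  u <- (t_pos - spec$tau) / spec$sigma
  h <- ifelse(t_pos >= spec$tau, exp(1) * u^2 * exp(-u^2), 0)
  box_len <- max(1L, round(spec$duration * fs))
  single <- convolve_causal(c(rep(1, box_len),
                              numeric(length(h))), h)
  peak <- max(single)
  # The indicator is rebuilt from onsets with the kernel's own boxcar
  # duration, so the "duration" parameter governs the convolution.
  ev <- stim[stim$condition == condition, ]
  s <- numeric(n_time)
  tt <- (seq_len(n_time) - 1) / fs
  for (i in seq_len(nrow(ev))) {
    s[tt >= ev$onset[i] & tt < ev$onset[i] + spec$duration] <- 1
  }
  convolve_causal(s, h)[seq_len(n_time)] / peak
}

# Causal discrete convolution, output aligned with the first argument.
convolve_causal <- function(x, h) {
  out <- convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_along(x)]
}

#' Convert raw intensity to optical density
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, so a
#' constant trace has OD identically zero.
#'
#' @param rec An `fnirs_recording` (all intensities strictly positive).
#' @return A list of class `fnirs_od` with `values` (array time x channel
#'   x wavelength), `fs` and `channels`.
#' @export
intensity_to_od <- function(rec) {
  d <- rec$data
  n_ch <- dim(d)[2]
  for (i in seq_len(n_ch)) {
    for (w in seq_len(dim(d)[3])) {
      trace <- d[, i, w]
      if (any(trace <= 0)) {
        stop("non-positive intensity in channel ", rec$channels$channel[i],
             " at wavelength index ", w,
             "; optical density is undefined")
      }
      d[, i, w] <- -log(trace / mean(trace))
    }
  }
  structure(list(values = d, fs = rec$fs, channels = rec$channels),
            class = "fnirs_od")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of the given design order forward and
#' backward (zero phase; the effective attenuation order is doubled,
#' which is the documented convention here). DC gain is 1.
#'
#' @param x Numeric vector, or an `fnirs_od` whose every trace is
#'   filtered.
#' @param fs Sampling rate (Hz); taken from the object when `x` is an
#'   `fnirs_od`.
#' @param cutoff Cut-off frequency (Hz), default 0.5.
#' @param order Filter design order, default 6.
#' @return Same shape as the input.
#' @export
lowpass_filter <- function(x, fs = NULL, cutoff = 0.5, order = 6) {
  if (inherits(x, "fnirs_od")) {
    for (i in seq_len(dim(x$values)[2])) {
      for (w in seq_len(dim(x$values)[3])) {
        x$values[, i, w] <- lowpass_filter(x$values[, i, w], x$fs,
                                           cutoff, order)
      }
    }
    return(x)
  }
  if (is.null(fs)) stop("fs is required for a bare numeric trace")
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cutoff")
  if (length(x) < 3 * (order + 1)) {
    stop("trace too short for the filter's warm-up")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # Filter around the DC level: filtfilt starts from zero state, so a
  # raw offset would ring at the trace edges.
  m <- mean(x)
  m + signal::filtfilt(bf, x - m)
}

#' Optical density to haemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law without pathlength correction:
#' per channel, the 2 x 2 extinction system at 760/850 nm is solved with
#' the source-detector separation (cm) as the only distance scaling, so
#' the returned concentration changes carry effective (pathlength-free)
#' molar units.
#'
#' @param od An `fnirs_od`.
#' @param extinction Extinction matrix (see [extinction_coefficients()]).
#' @return A list of class `fnirs_conc` with `hbo` and `hbr` (matrices
#'   time x channel), `fs` and `channels`.
#' @export
od_to_conc <- function(od, extinction = extinction_coefficients()) {
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  einv <- solve(extinction)
  n_time <- dim(od$values)[1]
  n_ch <- dim(od$values)[2]
  hbo <- hbr <- matrix(0, n_time, n_ch)
  for (i in seq_len(n_ch)) {
    d_cm <- od$channels$separation_mm[i] / 10
    conc <- od$values[, i, ] %*% t(einv) / d_cm
    hbo[, i] <- conc[, 1]
    hbr[, i] <- conc[, 2]
  }
  structure(list(hbo = hbo, hbr = hbr, fs = od$fs,
                 channels = od$channels),
            class = "fnirs_conc")
}

#' Select the short-separation regressor for a long channel
#'
#' Returns the index of the short-separation trace with the highest
#' Pearson correlation with the long channel's trace; ties break towards
#' the first label in order.
#'
#' @param long_trace Numeric vector.
#' @param short_traces Matrix with one column per candidate.
#' @param labels Optional candidate labels (default column order).
#' @return List with `index`, `label` and `correlation`.
#' @export
select_ss_regressor <- function(long_trace, short_traces, labels = NULL) {
  if (is.null(dim(short_traces))) {
    short_traces <- matrix(short_traces, ncol = 1)
  }
  if (ncol(short_traces) == 0) stop("no short-separation candidates")
  if (is.null(labels)) labels <- as.character(seq_len(ncol(short_traces)))
  r <- apply(short_traces, 2, function(s) {
    if (sd(s) == 0 || sd(long_trace) == 0) return(-Inf)
    cor(long_trace, s)
  })
  idx <- which(r == max(r))[1]
  list(index = idx, label = labels[idx], correlation = r[idx])
}

# Ordinary least squares with per-coefficient t statistics.
ols_fit <- function(y, X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * chol2inv(qr.R(qrx))
  se <- sqrt(diag(covb))
  tstat <- beta / se
  list(beta = beta, se = se, tstat = tstat,
       pvalue = 2 * pt(-abs(tstat), df), sigma2 = sigma2, df = df)
}

#' Fit the task GLM for one channel
#'
#' Ordinary-least-squares GLM of a channel's HbO2 and HbR concentration
#' series on the condition regressors (modified-gamma kernels convolved
#' with the stimulus boxcars), an optional short-separation regressor
#' (modelling superficial physiology), an intercept and a linear drift.
#' The estimated HRF per condition is the fitted beta times the kernel
#' over -2..12 s, baseline-corrected by subtracting its mean over
#' -2..0 s; the t statistic of each condition's HbO2 beta is reported.
#'
#' @param conc List with numeric vectors `hbo` and `hbr` for one channel.
#' @param stim An `fnirs_stim`.
#' @param fs Sampling rate (Hz).
#' @param ss Optional list with `hbo`/`hbr` short-separation traces.
#' @param spec_hbo,spec_hbr Kernel specifications.
#' @param drift Include a linear drift regressor (default `TRUE`).
#' @return A list of class `fnirs_glm` with `coefficients` (tibble:
#'   `chromophore`, `condition`, `beta`, `se`, `tstat`, `pvalue`),
#'   `sigma2` per chromophore, and `hrf` (tibble: `time`, `condition`,
#'   `chromophore`, `value`).
#' @export
glm_fit <- function(conc, stim, fs, ss = NULL,
                    spec_hbo = hrf_spec("hbo"), spec_hbr = hrf_spec("hbr"),
                    drift = TRUE) {
  n_time <- length(conc$hbo)
  conds <- sort(unique(stim$condition))
  coefs <- list()
  hrfs <- list()
  sigma2 <- c()
  for (chrom in c("hbo", "hbr")) {
    spec <- if (chrom == "hbo") spec_hbo else spec_hbr
    regs <- vapply(conds, function(cc)
      condition_regressor(stim, cc, spec, fs, n_time), numeric(n_time))
    X <- cbind(intercept = 1,
               if (drift) (seq_len(n_time) - 1) / (n_time - 1),
               regs,
               if (!is.null(ss)) ss[[chrom]])
    colnames(X) <- c("intercept", if (drift) "drift", conds,
                     if (!is.null(ss)) "ss")
    fit <- ols_fit(conc[[chrom]], X)
    keep <- match(conds, colnames(X))
    coefs[[chrom]] <- tibble::tibble(
      chromophore = chrom, condition = conds,
      beta = unname(fit$beta[keep]), se = unname(fit$se[keep]),
      tstat = unname(fit$tstat[keep]), pvalue = unname(fit$pvalue[keep])
    )
    sigma2[chrom] <- fit$sigma2
    kern <- hrf_basis(spec, fs)
    for (cc in conds) {
      tc <- fit$beta[match(cc, colnames(X))] * kern$value
      tc <- tc - mean(tc[kern$time >= -2 & kern$time < 0])
      hrfs[[paste(chrom, cc)]] <- tibble::tibble(
        time = kern$time, condition = cc, chromophore = chrom, value = tc)
    }
  }
  structure(list(coefficients = dplyr::bind_rows(coefs),
                 sigma2 = sigma2, hrf = dplyr::bind_rows(hrfs)),
            class = "fnirs_glm")
}

#' Run the full task pipeline on a recording
#'
#' Implements the task analysis chain: raw intensity to optical density,
#' exclusion of channels with SNR below `snr_threshold`, zero-phase
#' sixth-order Butterworth low-pass at 0.5 Hz, Beer-Lambert inversion
#' without pathlength correction, and a per-long-channel GLM in which the
#' short-separation channel most correlated with the long channel (HbO2
#' traces, within the same hemisphere) serves as a nuisance regressor.
#' When no short channel survives pruning the GLM runs without one, with
#' a message.
#'
#' @param rec An `fnirs_recording` of a task run.
#' @param stim The `fnirs_stim` used during acquisition.
#' @param rois Regions to analyse (default `"side"`, the motor coverage).
#' @param snr_threshold Channels below this raw-intensity SNR are pruned
#'   (default 5).
#' @param use_ss Include the short-separation regressor (default `TRUE`).
#' @return A tibble with one row per retained long channel and condition:
#'   `channel`, `roi`, `hemisphere`, `condition`, `ss_channel`,
#'   `beta_hbo`, `tstat_hbo`, `beta_hbr`, `tstat_hbr`.
#' @export
fit_task_glm <- function(rec, stim, rois = "side", snr_threshold = 5,
                         use_ss = TRUE) {
  ch <- rec$channels
  snr_all <- vapply(seq_len(nrow(ch)), function(i)
    channel_snr(rec$data[, i, ]), numeric(1))
  keep <- snr_all >= snr_threshold & ch$roi %in% rois
  if (!any(keep & ch$kind == "long")) {
    stop("no long channels survive SNR pruning in the requested ROI(s)")
  }
  idx <- which(keep)
  sub <- rec
  sub$data <- rec$data[, idx, , drop = FALSE]
  sub$channels <- ch[idx, ]
  od <- lowpass_filter(intensity_to_od(sub))
  conc <- od_to_conc(od)

  rows <- list()
  for (hemi in unique(sub$channels$hemisphere)) {
    long_i <- which(sub$channels$kind == "long" &
                      sub$channels$hemisphere == hemi)
    short_i <- which(sub$channels$kind == "short" &
                       sub$channels$hemisphere == hemi)
    for (i in long_i) {
      ss <- NULL
      ss_label <- NA_character_
      if (use_ss && length(short_i) > 0) {
        pick <- select_ss_regressor(
          conc$hbo[, i], conc$hbo[, short_i, drop = FALSE],
          labels = as.character(sub$channels$channel[short_i]))
        j <- short_i[pick$index]
        ss <- list(hbo = conc$hbo[, j], hbr = conc$hbr[, j])
        ss_label <- pick$label
      } else if (use_ss) {
        message("no short-separation channel survives pruning in ", hemi,
                " hemisphere; fitting without a nuisance regressor")
      }
      fit <- glm_fit(list(hbo = conc$hbo[, i], hbr = conc$hbr[, i]),
                     stim, rec$fs, ss = ss)
      co <- fit$coefficients
      for (cc in unique(co$condition)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = sub$channels$channel[i],
          roi = sub$channels$roi[i],
          hemisphere = hemi,
          condition = cc,
          ss_channel = ss_label,
          beta_hbo = co$beta[co$chromophore == "hbo" & co$condition == cc],
          tstat_hbo = co$tstat[co$chromophore == "hbo" &
                                 co$condition == cc],
          beta_hbr = co$beta[co$chromophore == "hbr" & co$condition == cc],
          tstat_hbr = co$tstat[co$chromophore == "hbr" &
                                 co$condition == cc]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
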