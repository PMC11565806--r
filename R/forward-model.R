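clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Normalised forward-model factors for one participant and region.
# The forehead is hairless: hair factors enter as 0 there.
forward_factors <- function(profile, region) {
  r <- combined_metric_spec()$ranges
  norm <- function(x, rng) clamp01((x - rng[1]) / (rng[2] - rng[1]))
  if (region == "forehead") {
    c(pigment = norm(profile$skin_pigmentation, r$pigmentation),
      color = 0, thickness = 0, type = 0)
  } else {
    thick <- profile[[paste0(region, "_avg_shaft_thickness")]]
    if (is.null(thick) || is.na(thick)) thick <- r$thickness[1]
    c(pigment = norm(profile$skin_pigmentation, r$pigmentation),
      color = norm(profile$hair_color, r$hair_color),
      thickness = norm(thick, r$thickness),
      type = norm(profile$hair_type, r$hair_type))
  }
}

#' Log10 light attenuation for a participant in a head region
#'
#' The forward model is linear on the log10-intensity scale: the
#' attenuation exponent is the weighted sum of the \[0, 1\]-normalised
#' factors (skin pigmentation, hair colour, shaft thickness, hair type)
#' with the per-region weights of the configuration. It is zero when all
#' factors sit at their range minima, non-decreasing in each factor, and
#' on the forehead depends on skin pigmentation only.
#'
#' @param profile One-row participant tibble.
#' @param region `"forehead"`, `"side"` or `"back"`.
#' @param config A [sim_config()].
#' @return A single non-negative log10 attenuation exponent.
#' @export
attenuation_exponent <- function(profile, region, config = sim_config()) {
  if (!region %in% c("forehead", "side", "back")) {
    stop("unknown region: ", region)
  }
  w <- config$attenuation[[region]]
  x <- forward_factors(profile, region)
  sum(w[names(x)] * x)
}

# Cardiac coupling deficit (before per-channel jitter and clipping).
coupling_deficit <- function(profile, region, config) {
  v <- config$cardiac$coupling_weights[[region]]
  x <- forward_factors(profile, region)
  sum(v[names(x)] * x)
}

# Per-channel realisation of the forward model for one participant:
# log-normal attenuation multipliers (hair lies under specific optodes)
# and jittered cardiac coupling. Drawn once per participant so that a
# fast-capping and a proper-capping run share the same channel pattern.
channel_effects <- function(profile, probe, config) {
  ch <- probe$channels
  n <- nrow(ch)
  mult <- exp(rnorm(n) * config$channel_lognorm_sd[ch$roi])
  atten <- vapply(seq_len(n), function(i)
    attenuation_exponent(profile, ch$roi[i], config), numeric(1)) * mult
  deficit <- vapply(seq_len(n), function(i)
    coupling_deficit(profile, ch$roi[i], config), numeric(1))
  jitter <- rnorm(n) * config$cardiac$coupling_jitter_sd
  list(attenuation = atten, deficit = deficit, jitter = jitter)
}

# Sum-of-random-sinusoids band noise, one unit-SD column per component.
rand_band_sinusoids <- function(n_time, fs, band, n_comp, k = 6) {
  t <- (seq_len(n_time) - 1) / fs
  f <- matrix(runif(k * n_comp, band[1], band[2]), k, n_comp)
  ph <- matrix(runif(k * n_comp, 0, 2 * pi), k, n_comp)
  out <- matrix(0, n_time, n_comp)
  for (j in seq_len(n_comp)) {
    s <- sin(outer(t, 2 * pi * f[, j]) +
               matrix(ph[, j], n_time, k, byrow = TRUE))
    out[, j] <- rowSums(s)
  }
  out <- sweep(out, 2, apply(out, 2, sd), "/")
  if (n_comp == 1) out[, 1] else out
}

#' Simulate a raw intensity recording
#'
#' Generates a continuous-wave intensity recording for one participant on
#' a probe. Each channel's intensity is
#' `baseline * 10^(-attenuation) * (1 + cardiac term) * (power scaling)`
#' plus Gaussian noise at the configured raw-unit floor. The cardiac term
#' (1.1 Hz fundamental plus one harmonic, 1% of the channel baseline by
#' default) is shared across the two wavelengths with a per-channel
#' coupling in \[0, 1\]; the uncoupled remainder is independent
#' cardiac-band noise per wavelength, so poor coupling degrades the scalp
#' coupling index without changing the mean. Shared slow superficial
#' physiology and, if a stimulus design is given, evoked haemodynamic
#' responses are injected in optical-density space through the same
#' Beer-Lambert forward relation the analysis inverts.
#'
#' @param profile One-row participant tibble.
#' @param probe An `fnirs_probe`.
#' @param duration_s Run length in seconds (> 0).
#' @param fs Sampling rate in Hz (> twice the cardiac frequency);
#'   default 10.2.
#' @param stim Optional `fnirs_stim`; evoked responses are injected into
#'   long channels of `evoked_rois`.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` consumes the ambient RNG stream.
#' @param capping `"proper"` (default) or `"fast"`; fast capping degrades
#'   attenuation and coupling per the configuration.
#' @param effects Optional precomputed [channel] effects (internal use by
#'   [generate_capping_pair()]).
#' @param evoked_rois Regions receiving evoked responses (default
#'   `"side"`, covering the motor areas of the montage).
#' @param run_label Stored label; defaults to `"task"` when `stim` is
#'   given, otherwise `"rest_proper_cap"`/`"rest_fast_cap"`.
#' @return An object of class `fnirs_recording`: list with `data`
#'   (array time x channel x wavelength), `fs`, `wavelengths`, `channels`
#'   (the probe channel table), `source_power_pct` (channel x wavelength),
#'   `run_label` and `participant_id`.
#' @export
generate_recording <- function(profile, probe, duration_s = 180, fs = 10.2,
                               stim = NULL, config = sim_config(),
                               seed = NULL,
                               capping = c("proper", "fast"),
                               effects = NULL, evoked_rois = "side",
                               run_label = NULL) {
  capping <- match.arg(capping)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (fs <= 2 * config$cardiac$freq_hz) {
    stop("fs must exceed twice the cardiac frequency")
  }
  if (!is.null(seed)) set.seed(seed)
  ch <- probe$channels
  n_ch <- nrow(ch)
  n_wl <- length(probe$wavelengths)
  n_time <- max(2L, round(duration_s * fs))
  t <- (seq_len(n_time) - 1) / fs

  if (is.null(effects)) effects <- channel_effects(profile, probe, config)
  atten <- effects$attenuation
  deficit <- effects$deficit
  if (capping == "fast") {
    atten <- atten * config$capping$attenuation_factor[ch$roi]
    deficit <- deficit + config$capping$coupling_drop[ch$roi]
  }
  coupling <- clamp01(1 - deficit + effects$jitter)

  base <- config$baseline_intensity * 10^(-atten)
  power_pct <- matrix(100, n_ch, n_wl)
  gain <- rep(1, n_ch)
  if (config$source_power_policy == "auto-scaled") {
    # The instrument drives sources at 25% nominally and raises LED power
    # (up to 100%) on attenuated channels, partially masking their loss.
    ref <- 25
    pct <- pmin(100, ref * 10^atten)
    power_pct[] <- pct
    gain <- pct / ref
  }

  # Shared cardiac waveform (fundamental + one harmonic), unit SD.
  ph <- runif(2, 0, 2 * pi)
  card <- sin(2 * pi * config$cardiac$freq_hz * t + ph[1]) +
    0.3 * sin(2 * pi * 2 * config$cardiac$freq_hz * t + ph[2])
  card <- card / sd(card)
  indep <- rand_band_sinusoids(n_time, fs, c(0.5, 2.5), n_ch * n_wl)

  # Slow superficial physiology shared by every channel (conc units).
  sys_trace <- rand_band_sinusoids(n_time, fs, config$systemic$band, 1)
  sys_gain <- exp(rnorm(n_ch) * 0.3)

  # Evoked concentration time courses (long channels of evoked_rois).
  hbo_ev <- hbr_ev <- NULL
  if (!is.null(stim)) {
    hbo_ev <- hbr_ev <- numeric(n_time)
    for (cond in unique(stim$condition)) {
      xo <- condition_regressor(stim, cond, hrf_spec("hbo"), fs, n_time)
      xr <- condition_regressor(stim, cond, hrf_spec("hbr"), fs, n_time)
      hbo_ev <- hbo_ev + config$evoked$hbo[[cond]] * xo
      hbr_ev <- hbr_ev + config$evoked$hbr[[cond]] * xr
    }
  }

  ext <- extinction_coefficients()
  data <- array(0, dim = c(n_time, n_ch, n_wl))
  for (i in seq_len(n_ch)) {
    d_cm <- ch$separation_mm[i] / 10
    evoked_here <- !is.null(stim) && ch$kind[i] == "long" &&
      ch$roi[i] %in% evoked_rois
    for (w in seq_len(n_wl)) {
      cardiac <- config$cardiac$rel_amplitude *
        (coupling[i] * card +
           (1 - coupling[i]) * indep[, (i - 1) * n_wl + w])
      od <- ext[w, "hbo"] * config$systemic$amplitude * sys_gain[i] *
        sys_trace * d_cm
      if (evoked_here) {
        od <- od + (ext[w, "hbo"] * hbo_ev + ext[w, "hbr"] * hbr_ev) * d_cm
      }
      data[, i, w] <- base[i] * gain[i] * (1 + cardiac) * exp(-od) +
        rnorm(n_time) * config$noise_floor_raw
    }
  }

  if (is.null(run_label)) {
    run_label <- if (!is.null(stim)) "task" else
      if (capping == "fast") "rest_fast_cap" else "rest_proper_cap"
  }
  structure(
    list(data = data, fs = fs, wavelengths = probe$wavelengths,
         channels = ch, source_power_pct = power_pct,
         run_label = run_label,
         participant_id = if ("id" %in% names(profile)) profile$id else NA),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat("<fnirs_recording> ", dim(x$data)[2], " channels x ",
      dim(x$data)[3], " wavelengths x ", dim(x$data)[1],
      " samples @ ", x$fs, " Hz (", x$run_label, ")\n", sep = "")
  invisible(x)
}

#' Simulate a fast-capping / proper-capping run pair
#'
#' Generates two three-minute resting-state recordings for the same
#' participant and probe: run 1 after a hasty cap placement (degraded
#' attenuation and optode-scalp coupling on the hairy regions per the
#' configuration) and run 2 after thorough hair adjustment. Both runs
#' share the same per-channel attenuation pattern, so the contrast
#' isolates the capping effect.
#'
#' @inheritParams generate_recording
#' @param duration_s Run length (default 180 s).
#' @return A list with elements `fast` and `proper`, both
#'   `fnirs_recording`s.
#' @export
generate_capping_pair <- function(profile, probe, config = sim_config(),
                                  seed = NULL, duration_s = 180,
                                  fs = 10.2) {
  if (!is.null(seed)) set.seed(seed)
  effects <- channel_effects(profile, probe, config)
  fast <- generate_recording(profile, probe, duration_s, fs, stim = NULL,
                             config = config, capping = "fast",
                             effects = effects)
  proper <- generate_recording(profile, probe, duration_s, fs, stim = NULL,
                               config = config, capping = "proper",
                               effects = effects)
  list(fast = fast, proper = proper)
}
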