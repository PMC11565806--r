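#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data forward model. The defaults
#' encode the study conditions the package emulates: a continuous-wave
#' system sampling at 10.2 Hz with a raw-unit noise floor of 6.8e-6
#' (equivalent to a detector NEP of 52 fW/sqrt(Hz)), a cardiac pulsation at
#' 1.1 Hz whose cross-wavelength coherence is degraded by hair factors, and
#' per-region light attenuation that grows with skin pigmentation, hair
#' colour, shaft thickness and curl type. Attenuation and coupling weights
#' are expressed per unit of the \[0, 1\]-normalised factor (see
#' [normalize_metric()]) on the log10-intensity scale; they are calibrated
#' so that cohort-level uncorrected signal means and scalp coupling indices
#' land near the reported resting-state levels (forehead ~0.33/0.95,
#' side ~0.17/0.90, back ~0.11/0.76) while reproducing the directions of
#' all factor effects. The forehead is hairless: only pigmentation
#' attenuates there.
#'
#' @param seed Integer seed used by generators that are asked to be
#'   self-seeding.
#' @param baseline_intensity Raw intensity of an unattenuated channel.
#' @param attenuation Named list (`forehead`, `side`, `back`) of named
#'   weight vectors (`pigment`, `color`, `thickness`, `type`), log10 units
#'   per normalised factor. All weights must be >= 0.
#' @param channel_lognorm_sd Per-region SD of the log-normal per-channel
#'   attenuation multiplier (hair happens under specific optodes, so
#'   channels within a region differ).
#' @param cardiac List: `freq_hz` (fundamental), `rel_amplitude` (fraction
#'   of the channel baseline), `coupling_weights` (per-region weight
#'   vectors; the per-channel coupling is 1 minus their weighted factor sum,
#'   clipped to \[0, 1\]), `coupling_jitter_sd` (per-channel spread).
#' @param noise_floor_raw Additive Gaussian noise SD in raw units
#'   (default 6.8e-6, the device-equivalent input noise).
#' @param source_power_policy `"fixed"` (all sources at 100%) or
#'   `"auto-scaled"` (the instrument raises LED power on attenuated
#'   channels, so uncorrected and corrected means diverge).
#' @param evoked List with `hbo` and `hbr`: named per-condition peak
#'   concentration-change amplitudes (molar, effective units given that the
#'   Beer-Lambert inversion applies no pathlength correction).
#' @param systemic List: `amplitude` (molar-equivalent SD of the shared
#'   superficial physiology injected into every channel) and `band` (Hz)
#'   of its spectral content.
#' @param capping List describing how a hasty cap placement degrades the
#'   recording relative to a thorough one: `attenuation_factor`
#'   (multiplier >= 1 on the attenuation exponent per region) and
#'   `coupling_drop` (subtracted from cardiac coupling per region).
#' @param pigment_color_dependence Latent Gaussian-copula correlation
#'   between skin pigmentation and hair colour in the cohort generator.
#' @param priors Categorical priors, see [participant_priors()].
#' @return A list of class `fnirs_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       baseline_intensity = 0.55,
                       attenuation = list(
                         forehead = c(pigment = 0.85, color = 0,
                                      thickness = 0, type = 0),
                         side = c(pigment = 0.55, color = 0.30,
                                  thickness = 0.20, type = 0.12),
                         back = c(pigment = 0.60, color = 0.45,
                                  thickness = 0.30, type = 0.15)
                       ),
                       channel_lognorm_sd = c(forehead = 0.25, side = 0.55,
                                              back = 0.65),
                       cardiac = list(
                         freq_hz = 1.1,
                         rel_amplitude = 0.01,
                         coupling_weights = list(
                           forehead = c(pigment = 0.04, color = 0,
                                        thickness = 0, type = 0),
                           side = c(pigment = 0.10, color = 0.15,
                                    thickness = 0.10, type = 0.15),
                           back = c(pigment = 0.10, color = 0.20,
                                    thickness = 0.15, type = 0.20)
                         ),
                         coupling_jitter_sd = 0.08
                       ),
                       noise_floor_raw = 6.8e-6,
                       source_power_policy = c("fixed", "auto-scaled"),
                       evoked = list(
                         hbo = c(left = 1e-6, right = 1e-6),
                         hbr = c(left = -0.3e-6, right = -0.3e-6)
                       ),
                       systemic = list(amplitude = 0.3e-6,
                                       band = c(0.05, 0.4)),
                       capping = list(
                         attenuation_factor = c(forehead = 1.00,
                                                side = 1.10, back = 1.05),
                         coupling_drop = c(forehead = 0.00, side = 0.09,
                                           back = 0.08)
                       ),
                       pigment_color_dependence = 0.4,
                       priors = participant_priors()) {
  source_power_policy <- match.arg(source_power_policy)
  for (region in names(attenuation)) {
    if (any(attenuation[[region]] < 0)) {
      stop("attenuation weights must be non-negative")
    }
  }
  if (baseline_intensity <= 0) stop("baseline_intensity must be positive")
  if (noise_floor_raw <= 0) stop("noise_floor_raw must be positive")
  if (any(unlist(cardiac$coupling_weights) < 0)) {
    stop("coupling weights must be non-negative")
  }
  validate_priors(priors)
  structure(
    list(seed = as.integer(seed),
         baseline_intensity = baseline_intensity,
         attenuation = attenuation,
         channel_lognorm_sd = channel_lognorm_sd,
         cardiac = cardiac,
         noise_floor_raw = noise_floor_raw,
         source_power_policy = source_power_policy,
         evoked = evoked,
         systemic = systemic,
         capping = capping,
         pigment_color_dependence = pigment_color_dependence,
         priors = priors),
    class = "fnirs_sim_config"
  )
}

#' Default categorical priors for the cohort generator
#'
#' Prior probabilities for the ordinal scales, chosen so the implied means
#' and SDs match the reported cohort (hair colour 3.2 (1.0) on the
#' Fischer-Saller 0-4 scale, hair type 1.8 (1.1) on the Andre Walker 0-4
#' scale, strand texture 1.7 (0.8) on the FIA 0-3 scale, regrouped
#' Fitzpatrick skin type 2.0 (0.9) on 1-3) and a 63/51 female/male split.
#' `p_no_hair` is the probability that a participant carries the "No Hair"
#' code on all three hair scales; the default cohort contains none, since
#' the reported scalp-hair moments describe haired scalps.
#'
#' @param hair_color,hair_type,hair_texture,skin_type Named probability
#'   vectors over the scale codes (names are the codes).
#' @param sex Named probabilities for `female`/`male`.
#' @param p_no_hair Probability of the all-zero hair coding.
#' @return A named list of priors.
#' @export
participant_priors <- function(hair_color = c(`1` = 0.04, `2` = 0.16,
                                              `3` = 0.36, `4` = 0.44),
                               hair_type = c(`1` = 0.55, `2` = 0.20,
                                             `3` = 0.15, `4` = 0.10),
                               hair_texture = c(`1` = 0.44, `2` = 0.42,
                                                `3` = 0.14),
                               skin_type = c(`1` = 0.35, `2` = 0.30,
                                             `3` = 0.35),
                               sex = c(female = 0.553, male = 0.447),
                               p_no_hair = 0) {
  list(hair_color = hair_color, hair_type = hair_type,
       hair_texture = hair_texture, skin_type = skin_type, sex = sex,
       p_no_hair = p_no_hair)
}

validate_priors <- function(priors) {
  for (nm in c("hair_color", "hair_type", "hair_texture", "skin_type",
               "sex")) {
    p <- priors[[nm]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("prior '", nm, "' must be non-negative and sum to 1")
    }
  }
  if (priors$p_no_hair < 0 || priors$p_no_hair > 1) {
    stop("p_no_hair must be a probability")
  }
  invisible(priors)
}
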