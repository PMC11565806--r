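#' Detector sensitivity (NEP) model
#'
#' Ties the device's measured raw-unit noise floor to its noise
#' equivalent power, allowing raw signal means to be expressed as
#' equivalent optical power at the detector. The study device has an NEP
#' of 52 fW/sqrt(Hz) at an equivalent raw signal input noise level of
#' 6.8e-6 and a detector area of 9.6 mm^2; the sqrt(Hz) bandwidth
#' normalisation is absorbed into that paired raw/power equivalence. The
#' pruning criterion demands an SNR of at least `margin_db` (default
#' 20 dB, i.e. two orders of magnitude in power) above the NEP.
#'
#' @param nep_w Noise equivalent power in W/sqrt(Hz) (default 52e-15).
#' @param noise_floor_raw Equivalent raw-unit noise level (default
#'   6.8e-6).
#' @param detector_area_mm2 Detector area (default 9.6 mm^2; recorded for
#'   reference).
#' @param margin_db SNR margin in dB (default 20).
#' @return A list of class `nep_model`.
#' @export
nep_model <- function(nep_w = 52e-15, noise_floor_raw = 6.8e-6,
                      detector_area_mm2 = 9.6, margin_db = 20) {
  if (nep_w <= 0) stop("nep_w must be positive")
  if (noise_floor_raw <= 0) stop("noise_floor_raw must be positive")
  if (margin_db < 0) stop("margin_db must be non-negative")
  structure(list(nep_w = nep_w, noise_floor_raw = noise_floor_raw,
                 detector_area_mm2 = detector_area_mm2,
                 margin_db = margin_db),
            class = "nep_model")
}

#' Convert raw signal units to equivalent optical power
#'
#' Linear rescaling through the device equivalence: a raw value equal to
#' the noise floor maps to the NEP, so
#' `power = raw * nep_w / noise_floor_raw` (watts).
#'
#' @param raw_value Raw signal values.
#' @param model An [nep_model()].
#' @return Equivalent optical power in W.
#' @examples
#' raw_to_power(6.8e-6)  # 52 fW, the device noise floor
#' @export
raw_to_power <- function(raw_value, model = nep_model()) {
  raw_value * model$nep_w / model$noise_floor_raw
}

#' SNR-margin pruning threshold in optical power
#'
#' `threshold = NEP * 10^(margin_db / 10)`: with the default 20 dB
#' margin the threshold sits two orders of magnitude above the noise
#' floor (1 pW NEP gives a 100 pW threshold).
#'
#' @param nep_w Noise equivalent power (W/sqrt(Hz)).
#' @param margin_db SNR margin in dB (default 20).
#' @return Threshold in W.
#' @export
snr_threshold <- function(nep_w, margin_db = 20) {
  if (margin_db < 0) stop("margin_db must be non-negative")
  nep_w * 10^(margin_db / 10)
}

#' Does a channel pass the NEP pruning criterion?
#'
#' A channel passes when its uncorrected signal mean, expressed as
#' equivalent optical power, is at least `margin_db` above the NEP.
#' The boundary passes ("at least" the margin).
#'
#' @param uncorrected_mean_raw Channel uncorrected signal means (raw
#'   units).
#' @param model An [nep_model()]; its raw/power equivalence converts the
#'   measured signal, which is a physical property of the recording.
#' @param threshold_nep_w NEP defining the pruning threshold (default:
#'   the model's own NEP). Passing a larger value asks how a less
#'   sensitive system would prune the same measured channels.
#' @return Logical vector.
#' @export
channel_pass <- function(uncorrected_mean_raw, model = nep_model(),
                         threshold_nep_w = model$nep_w) {
  raw_to_power(uncorrected_mean_raw, model) >=
    snr_threshold(threshold_nep_w, model$margin_db)
}

#' Pass percentages per combined-metric group
#'
#' For each combined hair-skin metric group, the percentage of channels
#' whose uncorrected signal mean clears the NEP + margin criterion, plus
#' the overall percentage of suboptimal (failing) channels.
#'
#' @param qualities Channel-quality tibble with a `usm` column.
#' @param groups Group id (1-5) per row of `qualities`.
#' @param model An [nep_model()].
#' @param threshold_nep_w NEP defining the pruning threshold (default:
#'   the model's own NEP); see [channel_pass()].
#' @return A list with `per_group` (tibble: `group`, `n`, `pass_pct`;
#'   empty groups yield `NA` and a warning) and `suboptimal_pct`.
#' @export
group_pass_percentages <- function(qualities, groups,
                                   model = nep_model(),
                                   threshold_nep_w = model$nep_w) {
  if (length(groups) != nrow(qualities)) {
    stop("every channel needs a group assignment")
  }
  pass <- channel_pass(qualities$usm, model, threshold_nep_w)
  per_group <- tibble::tibble(group = 1:5) %>%
    dplyr::left_join(
      tibble::tibble(group = as.integer(groups), pass = pass) %>%
        dplyr::group_by(.data$group) %>%
        dplyr::summarise(n = dplyr::n(),
                         pass_pct = 100 * mean(.data$pass)),
      by = "group")
  per_group$n[is.na(per_group$n)] <- 0L
  if (any(per_group$n == 0)) {
    warning("group(s) ",
            paste(per_group$group[per_group$n == 0], collapse = ", "),
            " contain no channels; pass percentage undefined")
  }
  list(per_group = per_group, suboptimal_pct = 100 * mean(!pass))
}

#' Pass-percentage curves across a detector-sensitivity sweep
#'
#' Recomputes the per-group pass percentages for a range of hypothetical
#' system sensitivities: each NEP value of `nep_grid` defines the pruning
#' threshold (margin unchanged) while the measured channel powers keep
#' the device's raw/power equivalence. Because the threshold is
#' increasing in NEP, every group's curve is non-increasing in NEP.
#'
#' @param qualities Channel-quality tibble with `usm`.
#' @param groups Group ids per row.
#' @param nep_grid Positive, sorted NEP values (W/sqrt(Hz)).
#' @param model Base [nep_model()] providing the raw/power equivalence
#'   and margin.
#' @return A tibble: `nep_w`, `group`, `n`, `pass_pct`.
#' @export
sensitivity_sweep <- function(qualities, groups, nep_grid,
                              model = nep_model()) {
  if (length(nep_grid) == 0) stop("nep_grid must be non-empty")
  if (any(nep_grid <= 0)) stop("nep_grid must be positive")
  if (is.unsorted(nep_grid)) stop("nep_grid must be sorted increasing")
  purrr::map_dfr(nep_grid, function(nep) {
    res <- suppressWarnings(
      group_pass_percentages(qualities, groups, model,
                             threshold_nep_w = nep))
    dplyr::mutate(res$per_group, nep_w = nep, .before = 1)
  })
}
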