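#' Generate a randomized ball-squeezing stimulus design
#'
#' Produces `n_trials` left-hand and `n_trials` right-hand squeezing
#' trials in fully randomized order. Each stimulus lasts `stim_duration`
#' seconds and consecutive stimuli are separated by an inter-stimulus
#' interval drawn uniformly from `isi_range`, so events never overlap.
#'
#' @param n_trials Trials per condition (>= 1); the study design uses 15.
#' @param seed Optional seed; `NULL` consumes the ambient RNG stream.
#' @param stim_duration Stimulus duration in seconds (default 5).
#' @param isi_range Inter-stimulus interval bounds in seconds
#'   (default `c(5, 15)`).
#' @return An object of class `fnirs_stim`: a tibble with columns `onset`
#'   (s), `duration` (s) and `condition` (`"left"`/`"right"`), with the
#'   total run length in attribute `run_duration`.
#' @examples
#' ev <- generate_events(15, seed = 1)
#' nrow(ev); range(diff(ev$onset))
#' @export
generate_events <- function(n_trials = 15, seed = NULL, stim_duration = 5,
                            isi_range = c(5, 15)) {
  if (length(n_trials) != 1 || is.na(n_trials) || n_trials < 1) {
    stop("n_trials must be a positive count")
  }
  if (!is.null(seed)) set.seed(seed)
  n_trials <- as.integer(n_trials)
  condition <- sample(rep(c("left", "right"), each = n_trials))
  n <- length(condition)
  isi <- runif(n + 1, isi_range[1], isi_range[2])
  onset <- isi[1] + cumsum(c(0, rep(stim_duration, n - 1)) +
                             c(0, isi[2:n]))
  run_duration <- onset[n] + stim_duration + isi[n + 1]
  out <- tibble::tibble(onset = onset, duration = stim_duration,
                        condition = condition)
  attr(out, "run_duration") <- run_duration
  class(out) <- c("fnirs_stim", class(out))
  out
}

#' Stimulus indicator sampled on a time grid
#'
#' Boxcar indicator of one condition's stimuli (1 during a stimulus,
#' 0 elsewhere), sampled at `fs` over `n_time` samples.
#'
#' @param stim An `fnirs_stim` design.
#' @param condition Condition name.
#' @param fs Sampling rate (Hz).
#' @param n_time Number of samples.
#' @return A numeric vector of length `n_time`.
#' @keywords internal
stim_indicator <- function(stim, condition, fs, n_time) {
  t <- (seq_len(n_time) - 1) / fs
  ind <- numeric(n_time)
  ev <- stim[stim$condition == condition, ]
  for (i in seq_len(nrow(ev))) {
    ind[t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]] <- 1
  }
  ind
}
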