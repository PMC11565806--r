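#' Build the study probe (montage)
#'
#' Constructs the optode array used throughout the package: per hemisphere,
#' the forehead carries 4 long-separation channels and 1 short-separation
#' channel, the side of the head 10 long and 2 short, and the back of the
#' head 4 long and 1 short, measured at 760 and 850 nm with nominal
#' separations of approximately 30 mm (long) and 8 mm (short). Optode
#' positions are logical 3-D coordinates (millimetres) laid out on a
#' schematic head; they identify optodes and regions rather than model
#' scalp geometry.
#'
#' @return An object of class `fnirs_probe`: a list with
#'   \describe{
#'     \item{optodes}{tibble with `label`, `type` (`"source"`/`"detector"`),
#'       `roi`, `hemisphere`, `x`, `y`, `z` (mm).}
#'     \item{channels}{tibble with `channel` (1-based id), `source`,
#'       `detector`, `roi` (`forehead`/`side`/`back`), `hemisphere`
#'       (`left`/`right`), `kind` (`long`/`short`) and `separation_mm`.}
#'     \item{wavelengths}{numeric, `c(760, 850)` nm.}
#'   }
#' @examples
#' pr <- generate_probe()
#' table(pr$channels$roi, pr$channels$kind)
#' @export
generate_probe <- function() {
  rois <- list(
    forehead = list(n_src = 2, n_det = 2,
                    pairs = cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                    short_at = 1,
                    centre = c(0, 90, 40)),
    side = list(n_src = 4, n_det = 4,
                pairs = cbind(c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4),
                              c(1, 2, 1, 2, 3, 2, 3, 4, 3, 4)),
                short_at = c(2, 3),
                centre = c(80, 0, 40)),
    back = list(n_src = 2, n_det = 2,
                pairs = cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                short_at = 1,
                centre = c(0, -90, 40))
  )

  optodes <- list()
  channels <- list()
  src_counter <- 0L
  det_counter <- 0L
  chan_counter <- 0L

  for (hemi in c("left", "right")) {
    side_sign <- if (hemi == "left") -1 else 1
    for (roi in names(rois)) {
      spec <- rois[[roi]]
      centre <- spec$centre
      if (roi != "side") centre[1] <- centre[1] + side_sign * 30
      if (roi == "side") centre[1] <- centre[1] * side_sign

      src_labels <- sprintf("S%d", src_counter + seq_len(spec$n_src))
      det_labels <- sprintf("D%d", det_counter + seq_len(spec$n_det))
      src_counter <- src_counter + spec$n_src
      det_counter <- det_counter + spec$n_det

      # Sources and detectors interleaved 30 mm apart along the ROI axis.
      src_pos <- t(vapply(seq_len(spec$n_src), function(i)
        centre + c(0, (i - 1) * 30 - 15 * (spec$n_src - 1), 0), numeric(3)))
      det_pos <- t(vapply(seq_len(spec$n_det), function(i)
        centre + c(side_sign * 30, (i - 1) * 30 - 15 * (spec$n_det - 1), 0),
        numeric(3)))

      optodes[[length(optodes) + 1L]] <- tibble::tibble(
        label = c(src_labels, det_labels),
        type = rep(c("source", "detector"), c(spec$n_src, spec$n_det)),
        roi = roi, hemisphere = hemi,
        x = c(src_pos[, 1], det_pos[, 1]),
        y = c(src_pos[, 2], det_pos[, 2]),
        z = c(src_pos[, 3], det_pos[, 3])
      )

      n_long <- nrow(spec$pairs)
      channels[[length(channels) + 1L]] <- tibble::tibble(
        channel = chan_counter + seq_len(n_long),
        source = src_labels[spec$pairs[, 1]],
        detector = det_labels[spec$pairs[, 2]],
        roi = roi, hemisphere = hemi,
        kind = "long", separation_mm = 30
      )
      chan_counter <- chan_counter + n_long

      # Short-separation detectors sit 8 mm from their source.
      ss_labels <- sprintf("D%d", det_counter + seq_along(spec$short_at))
      det_counter <- det_counter + length(spec$short_at)
      ss_pos <- src_pos[spec$short_at, , drop = FALSE]
      ss_pos[, 1] <- ss_pos[, 1] + side_sign * 8
      optodes[[length(optodes) + 1L]] <- tibble::tibble(
        label = ss_labels, type = "detector", roi = roi, hemisphere = hemi,
        x = ss_pos[, 1], y = ss_pos[, 2], z = ss_pos[, 3]
      )
      channels[[length(channels) + 1L]] <- tibble::tibble(
        channel = chan_counter + seq_along(spec$short_at),
        source = src_labels[spec$short_at],
        detector = ss_labels,
        roi = roi, hemisphere = hemi,
        kind = "short", separation_mm = 8
      )
      chan_counter <- chan_counter + length(spec$short_at)
    }
  }

  probe <- structure(
    list(
      optodes = dplyr::bind_rows(optodes),
      channels = dplyr::bind_rows(channels),
      wavelengths = c(760, 850)
    ),
    class = "fnirs_probe"
  )
  validate_probe(probe)
  probe
}

#' Validate a probe object
#'
#' Checks the montage invariants: per hemisphere the forehead has 4 long and
#' 1 short channel, the side 10 long and 2 short, the back 4 long and 1
#' short, and every channel references an existing source and detector.
#'
#' @param probe An `fnirs_probe`.
#' @return The probe, invisibly. Errors on violation.
#' @export
validate_probe <- function(probe) {
  stopifnot(inherits(probe, "fnirs_probe"))
  ch <- probe$channels
  expected <- c(forehead.long = 4, side.long = 10, back.long = 4,
                forehead.short = 1, side.short = 2, back.short = 1)
  for (hemi in c("left", "right")) {
    counts <- table(interaction(ch$roi[ch$hemisphere == hemi],
                                ch$kind[ch$hemisphere == hemi]))
    for (nm in names(expected)) {
      if (is.na(counts[nm]) || counts[nm] != expected[nm]) {
        stop("probe montage violates the per-hemisphere channel counts (",
             nm, " in ", hemi, " hemisphere)")
      }
    }
  }
  known <- probe$optodes$label
  if (!all(ch$source %in% known) || !all(ch$detector %in% known)) {
    stop("probe channels reference unknown optodes")
  }
  if (!identical(sort(probe$wavelengths), c(760, 850))) {
    stop("probe must carry the 760 and 850 nm wavelengths")
  }
  invisible(probe)
}

#' Subset a probe by region and hemisphere
#'
#' Restricts the montage to selected regions/hemispheres (keeping both
#' long and short channels there). The result no longer satisfies the
#' full-montage invariants and is meant for focused analyses, e.g.
#' simulating only the motor-area coverage during a task run.
#'
#' @param probe An `fnirs_probe`.
#' @param rois Regions to keep (default all).
#' @param hemispheres Hemispheres to keep (default both).
#' @return An `fnirs_probe` with the filtered channel table.
#' @export
filter_probe <- function(probe, rois = c("forehead", "side", "back"),
                         hemispheres = c("left", "right")) {
  keep <- probe$channels$roi %in% rois &
    probe$channels$hemisphere %in% hemispheres
  probe$channels <- probe$channels[keep, ]
  used <- unique(c(probe$channels$source, probe$channels$detector))
  probe$optodes <- probe$optodes[probe$optodes$label %in% used, ]
  probe
}

#' @export
print.fnirs_probe <- function(x, ...) {
  cat("<fnirs_probe> ", nrow(x$channels), " channels (",
      sum(x$channels$kind == "long"), " long, ",
      sum(x$channels$kind == "short"), " short), wavelengths ",
      paste(x$wavelengths, collapse = "/"), " nm\n", sep = "")
  invisible(x)
}
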