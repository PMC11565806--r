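#' Write a recording to a SNIRF (HDF5) file
#'
#' Serialises a probe, a raw continuous-wave intensity recording and an
#' optional stimulus design into the SNIRF layout: `/formatVersion`,
#' `/nirs/data1` (dataTimeSeries time x measurement, time vector, one
#' measurementList entry per channel x wavelength with dataType 1 = CW
#' amplitude), `/nirs/probe` (wavelengths, optode labels and 3-D
#' positions) and one `/nirs/stim<j>` group per condition. Source-power
#' percentages and the channel ROI/kind annotations have no canonical
#' SNIRF slot and are stored as datasets under `/nirs/metaDataTags`.
#'
#' @param probe An `fnirs_probe`.
#' @param recording An `fnirs_recording`.
#' @param stim Optional `fnirs_stim`; `NULL` writes no stim group.
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(probe, recording, stim = NULL, path) {
  stopifnot(inherits(probe, "fnirs_probe"),
            inherits(recording, "fnirs_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)

  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  id <- recording$participant_id
  h5w(if (is.na(id)) "unknown" else as.character(id),
      "nirs/metaDataTags/SubjectID")
  h5w("unknown", "nirs/metaDataTags/MeasurementDate")
  h5w("unknown", "nirs/metaDataTags/MeasurementTime")
  h5w("mm", "nirs/metaDataTags/LengthUnit")
  h5w("s", "nirs/metaDataTags/TimeUnit")
  h5w("Hz", "nirs/metaDataTags/FrequencyUnit")
  h5w(recording$run_label, "nirs/metaDataTags/runLabel")
  h5w(recording$source_power_pct, "nirs/metaDataTags/sourcePowerPct")
  ch <- recording$channels
  h5w(ch$roi, "nirs/metaDataTags/channelRoi")
  h5w(ch$hemisphere, "nirs/metaDataTags/channelHemisphere")
  h5w(ch$kind, "nirs/metaDataTags/channelKind")
  h5w(ch$separation_mm, "nirs/metaDataTags/channelSeparationMm")

  n_time <- dim(recording$data)[1]
  n_ch <- dim(recording$data)[2]
  n_wl <- dim(recording$data)[3]
  # Measurement order: channel-major, wavelength minor.
  dts <- matrix(0, n_time, n_ch * n_wl)
  for (i in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      dts[, (i - 1) * n_wl + w] <- recording$data[, i, w]
    }
  }
  rhdf5::h5createGroup(path, "nirs/data1")
  # rhdf5 reverses R dims on disk; writing the transpose leaves the file
  # with the canonical (time x measurement) C-order layout.
  h5w(t(dts), "nirs/data1/dataTimeSeries")
  h5w((seq_len(n_time) - 1) / recording$fs, "nirs/data1/time")

  src <- probe$optodes[probe$optodes$type == "source", ]
  det <- probe$optodes[probe$optodes$type == "detector", ]
  for (i in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      g <- sprintf("nirs/data1/measurementList%d", (i - 1) * n_wl + w)
      rhdf5::h5createGroup(path, g)
      h5w(match(ch$source[i], src$label), file.path(g, "sourceIndex"))
      h5w(match(ch$detector[i], det$label), file.path(g, "detectorIndex"))
      h5w(w, file.path(g, "wavelengthIndex"))
      h5w(1L, file.path(g, "dataType"))
      h5w(1L, file.path(g, "dataTypeIndex"))
    }
  }

  rhdf5::h5createGroup(path, "nirs/probe")
  h5w(probe$wavelengths, "nirs/probe/wavelengths")
  h5w(t(as.matrix(src[, c("x", "y", "z")])), "nirs/probe/sourcePos3D")
  h5w(t(as.matrix(det[, c("x", "y", "z")])), "nirs/probe/detectorPos3D")
  h5w(src$label, "nirs/probe/sourceLabels")
  h5w(det$label, "nirs/probe/detectorLabels")

  if (!is.null(stim) && nrow(stim) > 0) {
    conds <- sort(unique(stim$condition))
    for (j in seq_along(conds)) {
      g <- sprintf("nirs/stim%d", j)
      rhdf5::h5createGroup(path, g)
      h5w(conds[j], file.path(g, "name"))
      ev <- stim[stim$condition == conds[j], ]
      h5w(t(cbind(ev$onset, ev$duration, 1)), file.path(g, "data"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a SNIRF (HDF5) file
#'
#' Reads a continuous-wave SNIRF file back into the package types.
#' Mandatory fields (`dataTimeSeries`, `time`, the measurement list and
#' the probe wavelengths) raise a format error when missing; a data type
#' other than 1 (CW amplitude) is unsupported. Unknown optional groups
#' are ignored with a message. Channel ROI/kind annotations are
#' recovered from the metaDataTags written by [write_snirf()] when
#' present; otherwise the ROI is `"unknown"` and the kind is inferred
#' from the source-detector separation (short below 15 mm).
#'
#' @param path File path.
#' @return A list with `probe` (`fnirs_probe`), `recording`
#'   (`fnirs_recording`) and `stim` (`fnirs_stim` or `NULL`).
#' @export
read_snirf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  paths <- file.path(contents$group, contents$name)
  paths <- sub("^/", "", sub("^//", "/", paths))
  need <- c("nirs/data1/dataTimeSeries", "nirs/data1/time",
            "nirs/probe/wavelengths")
  missing <- setdiff(need, paths)
  if (length(missing) > 0) {
    stop("not a valid CW SNIRF file; missing: ",
         paste(missing, collapse = ", "))
  }
  h5r <- function(name) rhdf5::h5read(path, name)

  dts <- h5r("nirs/data1/dataTimeSeries")
  time <- as.numeric(h5r("nirs/data1/time"))
  # Orient as time x measurement regardless of the writer's dialect.
  if (length(time) > 2 && nrow(dts) != length(time) &&
      ncol(dts) == length(time)) {
    dts <- t(dts)
  }
  if (length(time) == 2 && nrow(dts) > 2) {
    time <- time[1] + (seq_len(nrow(dts)) - 1) * time[2]
  }
  fs <- 1 / median(diff(time))
  wavelengths <- as.numeric(h5r("nirs/probe/wavelengths"))

  ml_names <- grep("^nirs/data1/measurementList[0-9]+$", paths,
                   value = TRUE)
  if (length(ml_names) == 0) stop("missing SNIRF measurement list")
  k <- as.integer(sub(".*measurementList", "", ml_names))
  ml <- purrr::map_dfr(ml_names[order(k)], function(g) {
    dt <- as.integer(h5r(file.path(g, "dataType")))
    if (dt != 1) {
      stop("unsupported SNIRF data type ", dt,
           " (only CW amplitude, dataType 1, is supported)")
    }
    tibble::tibble(
      source = as.integer(h5r(file.path(g, "sourceIndex"))),
      detector = as.integer(h5r(file.path(g, "detectorIndex"))),
      wl = as.integer(h5r(file.path(g, "wavelengthIndex"))))
  })
  if (nrow(ml) != ncol(dts)) {
    stop("measurement list does not match dataTimeSeries columns")
  }

  orient3 <- function(m) if (nrow(m) == 3) t(m) else m
  src_pos <- orient3(h5r("nirs/probe/sourcePos3D"))
  det_pos <- orient3(h5r("nirs/probe/detectorPos3D"))
  src_labels <- if ("nirs/probe/sourceLabels" %in% paths) {
    as.character(h5r("nirs/probe/sourceLabels"))
  } else sprintf("S%d", seq_len(nrow(src_pos)))
  det_labels <- if ("nirs/probe/detectorLabels" %in% paths) {
    as.character(h5r("nirs/probe/detectorLabels"))
  } else sprintf("D%d", seq_len(nrow(det_pos)))

  tag <- function(name, default) {
    full <- paste0("nirs/metaDataTags/", name)
    if (full %in% paths) as.vector(h5r(full)) else default
  }
  pairs <- unique(ml[, c("source", "detector")])
  n_ch <- nrow(pairs)
  sep <- sqrt(rowSums((src_pos[pairs$source, , drop = FALSE] -
                         det_pos[pairs$detector, , drop = FALSE])^2))
  channels <- tibble::tibble(
    channel = seq_len(n_ch),
    source = src_labels[pairs$source],
    detector = det_labels[pairs$detector],
    roi = tag("channelRoi", rep("unknown", n_ch)),
    hemisphere = tag("channelHemisphere", rep("unknown", n_ch)),
    kind = tag("channelKind", ifelse(sep < 15, "short", "long")),
    separation_mm = as.numeric(tag("channelSeparationMm", sep))
  )

  n_wl <- length(wavelengths)
  data <- array(0, dim = c(nrow(dts), n_ch, n_wl))
  for (r in seq_len(nrow(ml))) {
    i <- which(channels$source == src_labels[ml$source[r]] &
                 channels$detector == det_labels[ml$detector[r]])
    data[, i, ml$wl[r]] <- dts[, r]
  }
  if (any(data < 0)) {
    warning("negative intensities found in ", path)
  }

  power <- tag("sourcePowerPct", NULL)
  if (is.null(power)) {
    power <- matrix(100, n_ch, n_wl)
  } else {
    power <- matrix(as.numeric(power), n_ch, n_wl)
  }
  if (any(power <= 0 | power > 100)) {
    stop("source power percentages must lie in (0, 100]")
  }

  optodes <- tibble::tibble(
    label = c(src_labels, det_labels),
    type = rep(c("source", "detector"),
               c(length(src_labels), length(det_labels))),
    roi = "unknown", hemisphere = "unknown",
    x = c(src_pos[, 1], det_pos[, 1]),
    y = c(src_pos[, 2], det_pos[, 2]),
    z = c(src_pos[, 3], det_pos[, 3])
  )
  probe <- structure(list(optodes = optodes, channels = channels,
                          wavelengths = wavelengths),
                     class = "fnirs_probe")

  stim_groups <- grep("^nirs/stim[0-9]+$", paths, value = TRUE)
  stim <- NULL
  if (length(stim_groups) > 0) {
    stim <- purrr::map_dfr(sort(stim_groups), function(g) {
      d <- h5r(file.path(g, "data"))
      if (is.null(dim(d))) d <- matrix(d, nrow = 1)
      if (nrow(d) == 3) d <- t(d)  # events x (onset, duration, amp)
      tibble::tibble(onset = d[, 1], duration = d[, 2],
                     condition = as.character(h5r(file.path(g, "name"))))
    }) %>% dplyr::arrange(.data$onset)
    attr(stim, "run_duration") <- max(time) + 1 / fs
    class(stim) <- c("fnirs_stim", class(stim))
  }

  known <- c(need, ml_names, "formatVersion",
             grep("^nirs(/metaDataTags|/probe|/stim|/data1)?",
                  paths, value = TRUE))
  unknown <- setdiff(paths, known)
  if (length(unknown) > 0) {
    message("ignoring unknown SNIRF groups: ",
            paste(unknown, collapse = ", "))
  }

  recording <- structure(
    list(data = data, fs = fs, wavelengths = wavelengths,
         channels = channels, source_power_pct = power,
         run_label = tag("runLabel", "unknown"),
         participant_id = tag("SubjectID", NA_character_)),
    class = "fnirs_recording")
  list(probe = probe, recording = recording, stim = stim)
}
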