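#' Specification of the combined hair-skin metric
#'
#' The combined metric averages four normalised participant factors chosen
#' to capture the joint impact of hair and skin on light attenuation:
#' average hair-shaft thickness (range 42-88 um), hair type (Andre Walker
#' scale 0-4), hair colour (Fischer-Saller scale 0-4) and skin pigmentation
#' (Melanin Index range 4.7-90). The ranges are the observed study extremes
#' used for \[0, 1\] normalisation.
#'
#' @return A list with per-metric `(min, max)` ranges and the metric count
#'   `m = 4`.
#' @export
combined_metric_spec <- function() {
  list(
    ranges = list(
      thickness = c(42, 88),
      hair_type = c(0, 4),
      hair_color = c(0, 4),
      pigmentation = c(4.7, 90)
    ),
    m = 4
  )
}

#' Encode categorical scale labels as ordinal codes
#'
#' Maps the documented vocabularies onto their numeric codes: hair colour
#' on the Fischer-Saller scale (No Hair 0, Grey/White 1, Blonde 2, Brown 3,
#' Red/Black 4), hair type on the Andre Walker scale (No Hair 0, Straight
#' 1, Wavy 2, Curly 3, Kinky 4), strand texture on the FIA scale (No Hair
#' 0, Fine 1, Medium 2, Coarse 3), and the Fitzpatrick skin phototypes
#' regrouped into three categories (I/II -> 1, III/IV -> 2, V/VI -> 3).
#' Matching is case-insensitive.
#'
#' @param labels Character vector of labels.
#' @param scale One of `"hair_color"`, `"hair_type"`, `"hair_texture"`,
#'   `"fitzpatrick"`.
#' @return Integer codes; unknown labels raise an error.
#' @examples
#' encode_scales(c("Kinky", "No Hair"), "hair_type")
#' encode_scales("V", "fitzpatrick")
#' @export
encode_scales <- function(labels, scale = c("hair_color", "hair_type",
                                            "hair_texture", "fitzpatrick")) {
  scale <- match.arg(scale)
  vocab <- switch(scale,
    hair_color = c("no hair" = 0, "grey" = 1, "gray" = 1, "white" = 1,
                   "grey / white" = 1, "grey/white" = 1, "blonde" = 2,
                   "brown" = 3, "red" = 4, "black" = 4,
                   "red / black" = 4, "red/black" = 4),
    hair_type = c("no hair" = 0, "straight" = 1, "wavy" = 2, "curly" = 3,
                  "kinky" = 4),
    hair_texture = c("no hair" = 0, "fine" = 1, "medium" = 2,
                     "coarse" = 3),
    fitzpatrick = c("i" = 1, "ii" = 1, "iii" = 2, "iv" = 2, "v" = 3,
                    "vi" = 3, "1" = 1, "2" = 1, "3" = 2, "4" = 2,
                    "5" = 3, "6" = 3)
  )
  key <- tolower(trimws(as.character(labels)))
  unknown <- !(key %in% names(vocab))
  if (any(unknown)) {
    stop("unknown ", scale, " label(s): ",
         paste(unique(labels[unknown]), collapse = ", "))
  }
  as.integer(unname(vocab[key]))
}

#' Normalise a metric to \[0, 1\]
#'
#' Applies `(x - min) / (max - min)`. Values outside the stated range are
#' clipped to \[0, 1\] with a warning: the ranges are the study's observed
#' extremes and new data may exceed them.
#'
#' @param x Numeric values.
#' @param min,max Range endpoints, `max > min`.
#' @param clip Clip out-of-range values (default `TRUE`).
#' @return Numeric values in \[0, 1\].
#' @export
normalize_metric <- function(x, min, max, clip = TRUE) {
  if (max <= min) stop("max must exceed min")
  z <- (x - min) / (max - min)
  out_of_range <- !is.na(z) & (z < 0 | z > 1)
  if (clip && any(out_of_range)) {
    warning(sum(out_of_range),
            " value(s) outside the normalisation range were clipped")
    z <- pmin(pmax(z, 0), 1)
  }
  z
}

#' Combined hair-skin metric
#'
#' Equal-weight average of the four normalised factors of
#' [combined_metric_spec()]. Higher values indicate more challenging
#' acquisition (more light absorbed by hair and skin).
#'
#' @param thickness Average hair-shaft thickness (um).
#' @param hair_type Andre Walker code (0-4).
#' @param hair_color Fischer-Saller code (0-4).
#' @param pigmentation Melanin Index.
#' @param spec A [combined_metric_spec()].
#' @return Metric values in \[0, 1\]; vectorised over the inputs.
#' @examples
#' combined_hair_skin_metric(65, 2, 3, 25.3)
#' @export
combined_hair_skin_metric <- function(thickness, hair_type, hair_color,
                                      pigmentation,
                                      spec = combined_metric_spec()) {
  r <- spec$ranges
  vals <- cbind(
    normalize_metric(thickness, r$thickness[1], r$thickness[2]),
    normalize_metric(hair_type, r$hair_type[1], r$hair_type[2]),
    normalize_metric(hair_color, r$hair_color[1], r$hair_color[2]),
    normalize_metric(pigmentation, r$pigmentation[1], r$pigmentation[2])
  )
  rowMeans(vals)
}

#' Assign combined-metric inclusivity groups
#'
#' Bins a combined hair-skin metric value into the five groups
#' \[0.15, 0.30), \[0.30, 0.45), \[0.45, 0.60), \[0.60, 0.75) and
#' \[0.75, 1\]. Bins are half-open on the right except the last, and
#' values below 0.15 fold into group 1 so that the assignment partitions
#' all of \[0, 1\].
#'
#' @param metric_value Values in \[0, 1\].
#' @return Integer group ids 1-5.
#' @examples
#' assign_group(c(0.1, 0.3, 0.5, 1))
#' @export
assign_group <- function(metric_value) {
  if (any(metric_value < 0 | metric_value > 1, na.rm = TRUE)) {
    stop("combined metric values must lie in [0, 1]")
  }
  findInterval(metric_value, c(0.30, 0.45, 0.60, 0.75)) + 1L
}

#' Add combined metric and group columns to a participant table
#'
#' The shaft thickness entering the combined metric is the average of the
#' side and back trichoscopy readings (the metric draws on both regions).
#' For "no hair" participants (all three hair codes 0) the thickness
#' contribution is taken at the range minimum, i.e. normalised 0.
#'
#' @param participants A participant tibble (see
#'   [generate_participants()]).
#' @param spec A [combined_metric_spec()].
#' @return The table with added `combined_metric` and `metric_group`.
#' @export
participant_metrics <- function(participants,
                                spec = combined_metric_spec()) {
  thick <- (participants$side_avg_shaft_thickness +
              participants$back_avg_shaft_thickness) / 2
  no_hair <- participants$hair_color == 0 & participants$hair_type == 0 &
    participants$hair_texture == 0
  thick[no_hair | is.na(thick)] <- spec$ranges$thickness[1]
  participants$combined_metric <- combined_hair_skin_metric(
    thick, participants$hair_type, participants$hair_color,
    participants$skin_pigmentation, spec
  )
  participants$metric_group <- assign_group(participants$combined_metric)
  participants
}
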