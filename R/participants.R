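#' Cohort factor moments
#'
#' Means and standard deviations of the continuous participant-level
#' factors used by the cohort generator: scalp-hair trichoscopy metrics per
#' region (side and back of the head), skin pigmentation (Melanin Index,
#' 0-99 scale), head measurements (cm) and age (years). Truncation bounds
#' are the observed study ranges where reported (shaft thickness 42-88 um,
#' pigmentation 4.7-90), otherwise mean +/- 3 SD floored at zero.
#'
#' @return A tibble with columns `factor`, `region`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
factor_moments <- function() {
  tri <- tibble::tribble(
    ~factor, ~region, ~mean, ~sd, ~lower, ~upper,
    "avg_num_hairs", "side", 160.7, 41.3, NA, NA,
    "avg_num_hairs", "back", 217.4, 47.2, NA, NA,
    "avg_shaft_thickness", "side", 62.2, 8.0, 42, 88,
    "avg_shaft_thickness", "back", 62.0, 7.9, 42, 88,
    "thin_pct", "side", 6.5, 5.5, NA, NA,
    "thin_pct", "back", 5.1, 4.6, NA, NA,
    "middle_pct", "side", 20.9, 10.7, NA, NA,
    "middle_pct", "back", 22.3, 10.6, NA, NA,
    "thick_pct", "side", 72.7, 13.3, NA, NA,
    "thick_pct", "back", 72.7, 13.5, NA, NA,
    "single_fu_pct", "side", 31.1, 12.1, NA, NA,
    "single_fu_pct", "back", 23.1, 9.6, NA, NA,
    "double_fu_pct", "side", 43.3, 10.2, NA, NA,
    "double_fu_pct", "back", 38.5, 9.5, NA, NA,
    "triple_fu_pct", "side", 25.6, 12.4, NA, NA,
    "triple_fu_pct", "back", 38.4, 13.6, NA, NA,
    "n_follicular_units", "side", 80.6, 18.2, NA, NA,
    "n_follicular_units", "back", 93.9, 17.3, NA, NA,
    "sinclair", "side", 2.5, 0.4, 1, 5,
    "sinclair", "back", 1.9, 0.4, 1, 5
  )
  whole <- tibble::tribble(
    ~factor, ~region, ~mean, ~sd, ~lower, ~upper,
    "skin_pigmentation", "whole", 25.3, 18.1, 4.7, 90,
    "head_circumference_cm", "whole", 57.1, 2.3, NA, NA,
    "nasion_inion_cm", "whole", 35.4, 2.4, NA, NA,
    "ear_to_ear_cm", "whole", 35.8, 2.7, NA, NA,
    "age", "whole", 26.4, 10.3, 18, 89
  )
  out <- dplyr::bind_rows(tri, whole)
  out$lower <- ifelse(is.na(out$lower), pmax(out$mean - 3 * out$sd, 0),
                      out$lower)
  out$upper <- ifelse(is.na(out$upper), out$mean + 3 * out$sd, out$upper)
  out
}

# Truncated-normal inverse CDF draw driven by uniforms in [0, 1].
qtruncnorm <- function(u, mean, sd, lower, upper) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(plo + u * (phi - plo))
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  qtruncnorm(runif(n), mean, sd, lower, upper)
}

# Map latent-normal quantiles onto a categorical prior.
categorical_from_u <- function(u, prior) {
  codes <- as.numeric(names(prior))
  codes[findInterval(u, cumsum(prior), left.open = TRUE) + 1L]
}

#' Generate a synthetic participant cohort
#'
#' Draws `n` participant profiles whose continuous factors follow truncated
#' normals with the cohort moments of [factor_moments()], whose categorical
#' factors follow the priors in `config$priors`, and in which skin
#' pigmentation, regrouped Fitzpatrick skin type and hair colour are tied
#' together through a latent Gaussian copula (pigmentation and skin type
#' strongly, pigmentation and hair colour with correlation
#' `config$pigment_color_dependence`). Derived fields respect the profile
#' invariants: per-category percentages sum to 100, cumulative hair
#' thickness equals density times shaft thickness times 1e-3, and a
#' "no hair" participant carries code 0 on all three hair scales.
#'
#' @param n Number of participants (>= 1).
#' @param config A [sim_config()].
#' @param seed Seed applied before drawing (default `config$seed`); pass
#'   `NULL` to consume the ambient RNG stream.
#' @return A tibble with one row per participant; trichoscopy columns are
#'   prefixed `side_` and `back_`.
#' @examples
#' ppl <- generate_participants(5, sim_config(seed = 7))
#' ppl[, c("id", "skin_pigmentation", "hair_color", "side_avg_num_hairs")]
#' @export
generate_participants <- function(n, config = sim_config(),
                                  seed = config$seed) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  validate_priors(config$priors)
  if (!is.null(seed)) set.seed(seed)
  fm <- factor_moments()
  moment <- function(f, r) fm[fm$factor == f & fm$region == r, ]

  # The dependence parameter targets the *realized* Pearson correlation.
  # Monotone marginal transforms (truncated-normal quantile, ordinal
  # thresholding) attenuate a latent Gaussian correlation, so the latent
  # value is inflated by the product of the marginal latent-observable
  # correlations, evaluated on a deterministic quantile grid.
  zg <- qnorm((seq_len(2001) - 0.5) / 2001)
  mp <- moment("skin_pigmentation", "whole")
  c_pig <- cor(qtruncnorm(pnorm(zg), mp$mean, mp$sd, mp$lower, mp$upper),
               zg)
  c_col <- cor(categorical_from_u(pnorm(zg), config$priors$hair_color),
               zg)
  rho_c <- min(config$pigment_color_dependence / (c_pig * c_col), 0.99)
  rho_st <- 0.85  # skin type is a coarse visual reading of pigmentation

  z_pig <- rnorm(n)
  z_col <- rho_c * z_pig + sqrt(1 - rho_c^2) * rnorm(n)
  z_st <- rho_st * z_pig + sqrt(1 - rho_st^2) * rnorm(n)

  m <- moment("skin_pigmentation", "whole")
  pigment <- qtruncnorm(pnorm(z_pig), m$mean, m$sd, m$lower, m$upper)
  pr <- config$priors
  hair_color <- categorical_from_u(pnorm(z_col), pr$hair_color)
  skin_type <- categorical_from_u(pnorm(z_st), pr$skin_type)
  hair_type <- categorical_from_u(runif(n), pr$hair_type)
  hair_texture <- categorical_from_u(runif(n), pr$hair_texture)
  no_hair <- runif(n) < pr$p_no_hair
  hair_color[no_hair] <- 0
  hair_type[no_hair] <- 0
  hair_texture[no_hair] <- 0

  draw <- function(f, r) {
    m <- moment(f, r)
    rtruncnorm(n, m$mean, m$sd, m$lower, m$upper)
  }
  out <- tibble::tibble(
    id = sprintf("sub-%03d", seq_len(n)),
    age = draw("age", "whole"),
    sex = categorical_from_u(runif(n),
                             setNames(pr$sex, seq_along(pr$sex))),
    head_circumference_cm = draw("head_circumference_cm", "whole"),
    nasion_inion_cm = draw("nasion_inion_cm", "whole"),
    ear_to_ear_cm = draw("ear_to_ear_cm", "whole"),
    skin_pigmentation = pigment,
    skin_type = skin_type,
    hair_color = hair_color,
    hair_type = hair_type,
    hair_texture = hair_texture
  )
  out$sex <- c("female", "male")[out$sex]

  for (region in c("side", "back")) {
    num <- draw("avg_num_hairs", region)
    thick <- draw("avg_shaft_thickness", region)
    pct <- cbind(draw("thin_pct", region), draw("middle_pct", region),
                 draw("thick_pct", region))
    pct <- pmax(pct, 0.1)
    pct <- 100 * pct / rowSums(pct)
    fu <- cbind(draw("single_fu_pct", region), draw("double_fu_pct", region),
                draw("triple_fu_pct", region))
    fu <- pmax(fu, 0.1)
    fu <- 100 * fu / rowSums(fu)
    block <- tibble::tibble(
      avg_num_hairs = num,
      avg_shaft_thickness = thick,
      thin_pct = pct[, 1], middle_pct = pct[, 2], thick_pct = pct[, 3],
      single_fu_pct = fu[, 1], double_fu_pct = fu[, 2],
      triple_fu_pct = fu[, 3],
      cumulative_thickness = num * thick * 1e-3,
      n_follicular_units = draw("n_follicular_units", region),
      sinclair = draw("sinclair", region)
    )
    names(block) <- paste0(region, "_", names(block))
    out <- dplyr::bind_cols(out, block)
  }
  validate_participants(out)
  out
}

#' Validate a participant table
#'
#' Enforces the profile invariants: ordinal codes inside their scales
#' (hair colour and type 0-4, strand texture 0-3, regrouped skin type 1-3),
#' "no hair" coded as zero on all three hair scales simultaneously,
#' per-category percentages summing to 100 +/- 0.5, and cumulative hair
#' thickness equal to density x shaft thickness x 1e-3 (tolerance 1e-6).
#'
#' @param participants A participant tibble.
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_participants <- function(participants) {
  p <- participants
  chk <- function(ok, msg) if (!all(ok, na.rm = FALSE)) stop(msg)
  chk(p$hair_color %in% 0:4, "hair_color outside the 0-4 scale")
  chk(p$hair_type %in% 0:4, "hair_type outside the 0-4 scale")
  chk(p$hair_texture %in% 0:3, "hair_texture outside the 0-3 scale")
  chk(p$skin_type %in% 1:3, "skin_type outside the regrouped 1-3 scale")
  chk(p$skin_pigmentation >= 0 & p$skin_pigmentation <= 99,
      "skin_pigmentation outside the 0-99 melanin index scale")
  chk(p$sex %in% c("female", "male"), "sex must be female/male")
  zero <- (p$hair_color == 0) | (p$hair_type == 0) | (p$hair_texture == 0)
  all_zero <- (p$hair_color == 0) & (p$hair_type == 0) &
    (p$hair_texture == 0)
  chk(!zero | all_zero,
      "'no hair' must be coded 0 on all three hair scales at once")
  for (region in c("side", "back")) {
    g <- function(f) p[[paste0(region, "_", f)]]
    if (is.null(g("avg_num_hairs"))) next
    chk(abs(g("thin_pct") + g("middle_pct") + g("thick_pct") - 100) <= 0.5,
        paste0(region, " thickness percentages do not sum to 100"))
    chk(abs(g("single_fu_pct") + g("double_fu_pct") + g("triple_fu_pct")
            - 100) <= 0.5,
        paste0(region, " follicular-unit percentages do not sum to 100"))
    chk(abs(g("cumulative_thickness") -
              g("avg_num_hairs") * g("avg_shaft_thickness") * 1e-3) <= 1e-6,
        paste0(region, " cumulative thickness inconsistent with density ",
               "and shaft thickness"))
  }
  invisible(participants)
}
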