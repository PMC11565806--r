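#' Channel-quality tables for a synthetic cohort
#'
#' Generates, for each participant, a fast-capping/proper-capping pair of
#' resting recordings and returns the stacked channel-quality tables of
#' both runs. Per-participant seeds are derived from `seed` so the cohort
#' is reproducible while participants differ.
#'
#' @param participants Participant tibble.
#' @param probe An `fnirs_probe`.
#' @param config A [sim_config()].
#' @param duration_s Resting-run length in seconds (default 180; shorter
#'   runs are useful for large replicate studies and leave the mean-based
#'   metrics essentially unchanged).
#' @param fs Sampling rate (Hz).
#' @param seed Base seed.
#' @param runs `"both"` (default) or `"proper"` to skip the fast-capping
#'   run.
#' @param sci Compute the scalp coupling index (default `TRUE`); see
#'   [channel_quality()].
#' @return A list with `run1` (fast capping) and `run2` (proper capping)
#'   quality tibbles; `run1` is `NULL` when `runs = "proper"`.
#' @export
cohort_quality <- function(participants, probe, config = sim_config(),
                           duration_s = 180, fs = 10.2,
                           seed = config$seed,
                           runs = c("both", "proper"), sci = TRUE) {
  runs <- match.arg(runs)
  q1 <- list()
  q2 <- list()
  for (i in seq_len(nrow(participants))) {
    profile <- participants[i, ]
    set.seed(seed + i)
    effects <- channel_effects(profile, probe, config)
    if (runs == "both") {
      rec1 <- generate_recording(profile, probe, duration_s, fs,
                                 config = config, capping = "fast",
                                 effects = effects)
      q1[[i]] <- suppressWarnings(channel_quality(rec1, sci = sci))
    }
    rec2 <- generate_recording(profile, probe, duration_s, fs,
                               config = config, capping = "proper",
                               effects = effects)
    q2[[i]] <- suppressWarnings(channel_quality(rec2, sci = sci))
  }
  list(run1 = if (runs == "both") dplyr::bind_rows(q1) else NULL,
       run2 = dplyr::bind_rows(q2))
}

# Participant-level factor columns for a given region, named as in the
# association/regression tables.
region_factors <- function(participants, region) {
  base <- tibble::tibble(
    participant = participants$id,
    skin_pigmentation = participants$skin_pigmentation,
    skin_type = participants$skin_type,
    sex = as.numeric(participants$sex == "female"),
    head_circumference = participants$head_circumference_cm,
    nasion_inion = participants$nasion_inion_cm,
    ear_to_ear = participants$ear_to_ear_cm,
    age = participants$age
  )
  if (region == "forehead") return(base)
  pick <- function(f) participants[[paste0(region, "_", f)]]
  dplyr::bind_cols(base, tibble::tibble(
    avg_num_hairs = pick("avg_num_hairs"),
    avg_shaft_thickness = pick("avg_shaft_thickness"),
    thin_pct = pick("thin_pct"),
    middle_pct = pick("middle_pct"),
    thick_pct = pick("thick_pct"),
    single_fu_pct = pick("single_fu_pct"),
    double_fu_pct = pick("double_fu_pct"),
    triple_fu_pct = pick("triple_fu_pct"),
    cumulative_thickness = pick("cumulative_thickness"),
    n_follicular_units = pick("n_follicular_units"),
    sinclair = pick("sinclair"),
    hair_color = participants$hair_color,
    hair_type = participants$hair_type,
    hair_texture = participants$hair_texture
  ))
}

# Long-channel responses of one region joined with that region's factors.
roi_response <- function(quality, participants, roi,
                         response = "csm",
                         unit = c("channel", "participant")) {
  unit <- match.arg(unit)
  q <- quality[quality$roi == roi & quality$kind == "long", ]
  if (unit == "participant") {
    q <- q %>%
      dplyr::group_by(.data$participant) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(response), mean))
  }
  fac <- region_factors(participants, roi)
  dplyr::inner_join(q[, c("participant", response)], fac,
                    by = "participant")
}

#' Factor-by-factor association analysis of a quality metric
#'
#' For each participant-level factor measured in (or applying to) a
#' region, computes the Spearman correlation with the channel-wise
#' metric, the robust linear fit on the log10-scale response, and the
#' fold change between the 1st and 99th factor percentiles. P-values are
#' Benjamini-Hochberg adjusted within the region's family of factors
#' (significance threshold 0.01).
#'
#' @param quality A channel-quality tibble (proper-capping run).
#' @param participants Participant tibble.
#' @param roi Region (`"forehead"`, `"side"`, `"back"`).
#' @param response Metric column on the log10 scale (default `"csm"`).
#' @param unit `"channel"` (default; channel-wise rows) or
#'   `"participant"` (per-participant means).
#' @return A tibble: `factor`, `fold_change`, `rho`, `p_value`
#'   (BH-adjusted), `slope`, `intercept`.
#' @export
factor_association_table <- function(quality, participants, roi,
                                     response = "csm",
                                     unit = "channel") {
  dat <- roi_response(quality, participants, roi, response, unit)
  factors <- setdiff(names(dat), c("participant", response))
  rows <- purrr::map_dfr(factors, function(f) {
    x <- dat[[f]]
    y <- dat[[response]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0) {
      # A factor without variation in this cohort carries no information.
      return(tibble::tibble(factor = f, fold_change = NA_real_,
                            rho = NA_real_, p_value = NA_real_,
                            slope = NA_real_, intercept = NA_real_))
    }
    sp <- spearman(x[ok], y[ok])
    fit <- robust_linfit(x[ok], y[ok])
    fc <- fold_change(fit, x[ok])
    tibble::tibble(factor = f, fold_change = fc$fold_change,
                   rho = sp$rho, p_value = sp$p,
                   slope = fit$slope, intercept = fit$intercept)
  })
  rows$p_value <- as.numeric(bh_adjust(rows$p_value))
  rows
}

# Priority order used when screening correlated predictors: objective,
# interpretable measurements first (melanin index over Fitzpatrick type,
# trichoscopy over visual codes), matching the study's stated choice.
default_predictor_priority <- c(
  "skin_pigmentation", "avg_num_hairs", "avg_shaft_thickness",
  "hair_color", "hair_type", "sex", "head_circumference", "age",
  "cumulative_thickness", "n_follicular_units", "hair_texture",
  "skin_type", "sinclair", "thin_pct", "middle_pct", "thick_pct",
  "single_fu_pct", "double_fu_pct", "triple_fu_pct", "nasion_inion",
  "ear_to_ear"
)

#' Multicollinearity-screened robust regression of a quality metric
#'
#' Assembles the candidate predictors for a region, drops one of every
#' pair correlated above 0.5 in absolute value (keeping the
#' higher-priority, more objective metric), fits the robust multiple
#' regression and reports the Tables-5/6-shaped result.
#'
#' @inheritParams factor_association_table
#' @param predictors Candidate predictor names (default: the study's
#'   regression set — hair density and shaft thickness where measured,
#'   pigmentation, hair colour, sex, head circumference, age).
#' @param r_threshold Screening threshold (default 0.5).
#' @return A [robust_multiple_regression()] tibble, with the retained
#'   predictor set in attribute `screened`.
#' @export
quality_regression_table <- function(quality, participants, roi,
                                     response = "csm",
                                     unit = "channel",
                                     predictors = NULL,
                                     r_threshold = 0.5) {
  dat <- roi_response(quality, participants, roi, response, unit)
  if (is.null(predictors)) {
    predictors <- if (roi == "forehead") {
      c("skin_pigmentation", "skin_type", "sex", "head_circumference",
        "age")
    } else {
      c("avg_num_hairs", "avg_shaft_thickness", "skin_pigmentation",
        "skin_type", "hair_color", "hair_texture", "sex",
        "head_circumference", "age")
    }
  }
  X <- as.matrix(dat[, predictors])
  varying <- colnames(X)[apply(X, 2, function(v) sd(v, na.rm = TRUE) > 0)]
  X <- X[, varying, drop = FALSE]
  keep <- multicollinearity_screen(
    X, r_threshold,
    priority = intersect(default_predictor_priority, varying))
  ok <- is.finite(dat[[response]]) &
    apply(is.finite(X[, keep, drop = FALSE]), 1, all)
  out <- robust_multiple_regression(X[ok, keep, drop = FALSE],
                                    dat[[response]][ok])
  attr(out, "screened") <- keep
  out
}

#' Run the end-to-end synthetic study
#'
#' Generates a cohort, resting capping pairs and task runs, computes
#' quality metrics and the combined hair-skin metric, and emits the
#' study-shaped result tables: factor associations and robust
#' regressions per region, the fast/proper capping comparison, the NEP
#' group pass percentages with a sensitivity sweep, and the task-GLM
#' regression. All outputs are written as CSV/TSV under `outdir`
#' together with a manifest recording the seed and configuration hash.
#'
#' @param n Cohort size.
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param rest_duration_s,task_trials Resting-run length and trials per
#'   task condition.
#' @param nep_grid Detector-sensitivity sweep (W/sqrt(Hz)).
#' @param unit Unit of analysis for association/regression tables.
#' @param run_glm Fit the task GLM stage (default `TRUE`).
#' @return (Invisibly) a list of all result tables plus `outdir`.
#' @export
run_study <- function(n = 30, config = sim_config(), outdir = tempdir(),
                      rest_duration_s = 180, task_trials = 15,
                      nep_grid = 10^seq(-14, -12, length.out = 9),
                      unit = "channel", run_glm = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  probe <- generate_probe()
  participants <- generate_participants(n, config)
  participants <- participant_metrics(participants)
  write_participants(participants, file.path(outdir, "participants.tsv"))

  qc <- cohort_quality(participants, probe, config,
                       duration_s = rest_duration_s)
  readr::write_csv(qc$run1, file.path(outdir, "qc_run1.csv"),
                   progress = FALSE)
  readr::write_csv(qc$run2, file.path(outdir, "qc_run2.csv"),
                   progress = FALSE)

  assoc <- list()
  regr <- list()
  for (roi in c("forehead", "side", "back")) {
    assoc[[roi]] <- factor_association_table(qc$run2, participants, roi,
                                             unit = unit) %>%
      dplyr::mutate(roi = roi, .before = 1)
    for (resp in c("csm", "sci_z")) {
      key <- paste(roi, resp, sep = "_")
      regr[[key]] <- quality_regression_table(
        qc$run2, participants, roi, response = resp, unit = unit) %>%
        dplyr::mutate(roi = roi, response = resp, .before = 1)
    }
  }
  assoc <- dplyr::bind_rows(assoc)
  regr <- dplyr::bind_rows(regr)
  readr::write_csv(assoc, file.path(outdir, "associations.csv"),
                   progress = FALSE)
  readr::write_csv(regr, file.path(outdir, "regressions.csv"),
                   progress = FALSE)

  capping <- purrr::map_dfr(c("forehead", "side", "back"), function(roi)
    dplyr::bind_rows(
      compare_runs(qc$run1, qc$run2, "sci", roi),
      compare_runs(qc$run1, qc$run2, "usm", roi)))
  readr::write_csv(capping, file.path(outdir, "capping.csv"),
                   progress = FALSE)

  groups <- participants$metric_group[
    match(qc$run2$participant, participants$id)]
  nep <- suppressWarnings(group_pass_percentages(qc$run2, groups))
  curves <- sensitivity_sweep(qc$run2, groups, nep_grid)
  readr::write_csv(nep$per_group, file.path(outdir, "nep_groups.csv"),
                   progress = FALSE)
  readr::write_csv(curves, file.path(outdir, "nep_curves.csv"),
                   progress = FALSE)

  glm_tab <- NULL
  glm_regr <- NULL
  if (run_glm) {
    rows <- list()
    for (i in seq_len(nrow(participants))) {
      set.seed(config$seed + 10000 + i)
      stim <- generate_events(task_trials)
      rec <- generate_recording(participants[i, ], probe,
                                duration_s = attr(stim, "run_duration"),
                                stim = stim, config = config)
      fit <- fit_task_glm(rec, stim)
      rows[[i]] <- fit %>%
        dplyr::mutate(participant = participants$id[i], .before = 1)
    }
    glm_tab <- dplyr::bind_rows(rows)
    readr::write_csv(glm_tab, file.path(outdir, "glm_channels.csv"),
                     progress = FALSE)
    per_part <- glm_tab %>%
      dplyr::group_by(.data$participant) %>%
      dplyr::summarise(beta_hbo = mean(.data$beta_hbo),
                       tstat_hbo = mean(.data$tstat_hbo))
    fac <- region_factors(participants, "side")
    dat <- dplyr::inner_join(per_part, fac, by = "participant")
    preds <- c("avg_num_hairs", "avg_shaft_thickness",
               "skin_pigmentation", "hair_color", "sex",
               "head_circumference", "age")
    # Keep only predictors that vary in this cohort, and require enough
    # participants for the model's degrees of freedom.
    preds <- preds[vapply(preds, function(p) sd(dat[[p]]) > 0,
                          logical(1))]
    if (nrow(dat) > length(preds) + 2) {
      glm_regr <- purrr::map_dfr(c("beta_hbo", "tstat_hbo"),
                                 function(resp)
        robust_multiple_regression(as.matrix(dat[, preds]),
                                   dat[[resp]]) %>%
          dplyr::mutate(response = resp, .before = 1))
    } else {
      message("cohort too small for the GLM factor regression; ",
              "writing an empty table")
      glm_regr <- tibble::tibble(response = character(),
                                 predictor = character(),
                                 estimate = numeric(), se = numeric(),
                                 tstat = numeric(), pvalue = numeric(),
                                 f2 = numeric(), vif = numeric())
    }
    readr::write_csv(glm_regr, file.path(outdir, "glm_regression.csv"),
                     progress = FALSE)
  }

  manifest <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("fnirsinc"))),
    paste0("seed: ", config$seed),
    paste0("n_participants: ", n),
    paste0("rest_duration_s: ", rest_duration_s),
    paste0("unit_of_analysis: ", unit),
    paste0("config_hash: ", rlang::hash(config))
  )
  writeLines(manifest, file.path(outdir, "manifest.txt"))

  invisible(list(outdir = outdir, participants = participants,
                 qc = qc, associations = assoc, regressions = regr,
                 capping = capping, nep_groups = nep$per_group,
                 nep_suboptimal_pct = nep$suboptimal_pct,
                 nep_curves = curves, glm = glm_tab,
                 glm_regression = glm_regr))
}

#' Render a human-readable study report
#'
#' Writes a markdown summary of a [run_study()] bundle (capping
#' improvements, significant associations at the 0.01 threshold with
#' their effect directions, Cohen's f-squared bands, NEP group
#' percentages) and the accompanying figures: violin plots of the binned
#' response, f-squared bars per region, and the NEP sensitivity curves.
#' Figures are regenerated from the bundle's saved tables only, so a
#' report can be rebuilt from disk at any time.
#'
#' @param bundle The list returned by [run_study()].
#' @param outdir Output directory (default: the bundle's).
#' @return Path of the written `report.md`, invisibly.
#' @export
study_report <- function(bundle, outdir = bundle$outdir) {
  if (is.null(bundle$qc) || is.null(bundle$associations)) {
    stop("bundle is missing required members")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Synthetic inclusivity study report", "")

  md <- c(md, "## Capping improvement", "",
          "Percent change in quality metrics from fast to proper capping:",
          "")
  cap <- bundle$capping
  for (r in seq_len(nrow(cap))) {
    md <- c(md, sprintf(
      "- %s / %s: %.2f (%.2f) to %.2f (%.2f), %+.1f%% (p = %.3g)",
      cap$roi[r], toupper(cap$metric[r]), cap$mean1[r], cap$sd1[r],
      cap$mean2[r], cap$sd2[r], cap$percent_increase[r],
      cap$p_paired_t[r]))
  }

  md <- c(md, "", "## Significant factor associations (BH p <= 0.01)", "")
  sig <- bundle$associations[bundle$associations$p_value <= 0.01, ]
  if (nrow(sig) == 0) {
    md <- c(md, "none")
  } else {
    for (r in seq_len(nrow(sig))) {
      md <- c(md, sprintf("- %s / %s: rho = %.2f, fold change %.1f",
                          sig$roi[r], sig$factor[r], sig$rho[r],
                          sig$fold_change[r]))
    }
  }

  md <- c(md, "", "## Effect sizes", "",
          paste("Cohen's f^2 bands: small >= 0.02, medium >= 0.15,",
                "large >= 0.35."), "")
  rg <- bundle$regressions
  big <- rg[rg$f2 >= 0.02, ]
  for (r in seq_len(nrow(big))) {
    band <- if (big$f2[r] >= 0.35) "large" else
      if (big$f2[r] >= 0.15) "medium" else "small"
    md <- c(md, sprintf("- %s / %s / %s: f^2 = %.2f (%s), t = %.1f",
                        big$roi[r], big$response[r], big$predictor[r],
                        big$f2[r], band, big$tstat[r]))
  }

  md <- c(md, "", "## NEP inclusivity", "",
          sprintf("Suboptimal channels at the device NEP: %.1f%%",
                  bundle$nep_suboptimal_pct), "")
  ng <- bundle$nep_groups
  for (r in seq_len(nrow(ng))) {
    md <- c(md, sprintf("- group %d (n = %d): %.1f%% pass", ng$group[r],
                        ng$n[r], ng$pass_pct[r]))
  }

  # Figures, rebuilt from the saved stage outputs.
  qc2 <- readr::read_csv(file.path(bundle$outdir, "qc_run2.csv"),
                         show_col_types = FALSE, progress = FALSE)
  parts <- read_participants(file.path(bundle$outdir,
                                       "participants.tsv"))
  dat <- roi_response(qc2, parts, "side")
  dat$bin <- factor(equal_width_bins(dat$skin_pigmentation))
  p1 <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$csm,
                                          fill = .data$bin)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.1, show.legend = FALSE) +
    ggplot2::labs(x = "skin pigmentation bin",
                  y = "corrected signal mean (log10)",
                  title = "Side of the head") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(outdir, "violin_side_pigmentation.png"), p1,
                  width = 5, height = 4, dpi = 120)

  p2 <- ggplot2::ggplot(rg, ggplot2::aes(x = .data$predictor,
                                         y = .data$f2)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.02, 0.15, 0.35),
                        linetype = "dashed") +
    ggplot2::facet_grid(response ~ roi) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Cohen's f^2", x = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(outdir, "effect_sizes.png"), p2,
                  width = 8, height = 5, dpi = 120)

  cv <- bundle$nep_curves
  p3 <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$nep_w,
                                         y = .data$pass_pct,
                                         colour = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "NEP (W/sqrt(Hz))", y = "% channels passing",
                  colour = "group") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(outdir, "nep_curves.png"), p3,
                  width = 6, height = 4, dpi = 120)

  path <- file.path(outdir, "report.md")
  writeLines(md, path)
  invisible(path)
}
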