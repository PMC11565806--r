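test_that("attenuation is zero at the factor minima and monotone", {
  cfg <- fixture_config()
  base <- fixture_cohort(1)[1, ]
  mini <- base
  mini$skin_pigmentation <- 4.7
  mini$hair_color <- 1; mini$hair_type <- 1; mini$hair_texture <- 1
  mini$side_avg_shaft_thickness <- 42
  mini$back_avg_shaft_thickness <- 42
  # hair colour/type scales start at 0 ("no hair"); set those too
  mini$hair_color <- 0; mini$hair_type <- 0; mini$hair_texture <- 0
  for (region in c("forehead", "side", "back")) {
    expect_equal(attenuation_exponent(mini, region, cfg), 0)
  }

  darker <- mini
  darker$skin_pigmentation <- 90
  for (region in c("forehead", "side", "back")) {
    expect_gt(attenuation_exponent(darker, region, cfg),
              attenuation_exponent(mini, region, cfg))
  }

  # The forehead is hairless: hair factors must not move it.
  hairy <- darker
  hairy$hair_color <- 4; hairy$hair_type <- 4; hairy$hair_texture <- 3
  hairy$side_avg_shaft_thickness <- 88
  expect_equal(attenuation_exponent(hairy, "forehead", cfg),
               attenuation_exponent(darker, "forehead", cfg))
  expect_gt(attenuation_exponent(hairy, "side", cfg),
            attenuation_exponent(darker, "side", cfg))
  expect_error(attenuation_exponent(hairy, "scalp", cfg), "unknown region")
})

test_that("recordings are bit-identical under a fixed seed", {
  cfg <- fixture_config()
  pr <- filter_probe(fixture_probe(), rois = "forehead")
  ppl <- fixture_cohort(1)
  a <- generate_recording(ppl[1, ], pr, 15, config = cfg, seed = 99)
  b <- generate_recording(ppl[1, ], pr, 15, config = cfg, seed = 99)
  expect_identical(a$data, b$data)
})

test_that("a noiseless, cardiac-free channel sits exactly at baseline", {
  cfg <- sim_config(seed = 1, baseline_intensity = 0.33,
                    noise_floor_raw = 1e-300)
  cfg$cardiac$rel_amplitude <- 0
  cfg$systemic$amplitude <- 0
  for (region in names(cfg$attenuation)) {
    cfg$attenuation[[region]][] <- 0
  }
  cfg$channel_lognorm_sd[] <- 0
  pr <- filter_probe(fixture_probe(), rois = "side",
                     hemispheres = "right")
  rec <- generate_recording(fixture_cohort(1)[1, ], pr, 12,
                            config = cfg, seed = 5)
  expect_equal(uncorrected_signal_mean(rec, rec$channels$channel[1]),
               0.33, tolerance = 1e-12)
})

test_that("perfect coupling without noise gives SCI of 1", {
  cfg <- sim_config(seed = 1, noise_floor_raw = 1e-300)
  for (region in names(cfg$cardiac$coupling_weights)) {
    cfg$cardiac$coupling_weights[[region]][] <- 0
  }
  cfg$cardiac$coupling_jitter_sd <- 0
  cfg$systemic$amplitude <- 0
  pr <- filter_probe(fixture_probe(), rois = "forehead",
                     hemispheres = "right")
  rec <- generate_recording(fixture_cohort(1)[1, ], pr, 60,
                            config = cfg, seed = 2)
  sci <- vapply(rec$channels$channel, function(c)
    scalp_coupling_index(rec, c), numeric(1))
  expect_true(all(abs(sci - 1) < 1e-9))
})

test_that("a cardiac-free recording has a null scalp coupling index", {
  cfg <- sim_config(seed = 1)
  cfg$cardiac$rel_amplitude <- 0  # noise floor only
  cfg$systemic$amplitude <- 0
  pr <- filter_probe(fixture_probe(), rois = "side",
                     hemispheres = "right")
  ppl <- fixture_cohort(1)
  scis <- c()
  set.seed(10)
  for (s in 1:12) {
    rec <- generate_recording(ppl[1, ], pr, 180, config = cfg)
    scis <- c(scis, vapply(rec$channels$channel, function(c)
      scalp_coupling_index(rec, c), numeric(1)))
  }
  expect_gt(mean(abs(scis) < 0.1), 0.95)
})

test_that("weaker optode coupling lowers the scalp coupling index", {
  cfg <- fixture_config()
  pr <- filter_probe(fixture_probe(), rois = "side",
                     hemispheres = "right")
  ppl <- fixture_cohort(1)
  sci_at_drop <- function(drop) {
    c2 <- cfg
    c2$capping$coupling_drop["side"] <- drop
    rec <- generate_recording(ppl[1, ], pr, 120, config = c2, seed = 31,
                              capping = "fast")
    mean(vapply(rec$channels$channel, function(c)
      scalp_coupling_index(rec, c), numeric(1)))
  }
  expect_gt(sci_at_drop(0), sci_at_drop(0.3))
  expect_gt(sci_at_drop(0.3), sci_at_drop(0.6))
})

test_that("the capping pair shows the study's improvement pattern", {
  cfg <- fixture_config()
  pr <- fixture_probe()
  ppl <- fixture_cohort(20)
  qc <- cohort_quality(ppl, pr, cfg, duration_s = 40, seed = 400)
  side_sci <- compare_runs(qc$run1, qc$run2, "sci", "side")
  expect_gt(side_sci$percent_increase, 0)
  expect_lt(side_sci$p_paired_t, 0.01)
  back_sci <- compare_runs(qc$run1, qc$run2, "sci", "back")
  expect_gt(back_sci$percent_increase, 0)
  # The hairless forehead is untouched by hair adjustment.
  fh_usm <- compare_runs(qc$run1, qc$run2, "usm", "forehead")
  expect_lt(abs(fh_usm$percent_increase), 2)
})

test_that("degradation-free capping pairs are exchangeable", {
  cfg <- fixture_config()
  cfg$capping$attenuation_factor[] <- 1
  cfg$capping$coupling_drop[] <- 0
  pr <- filter_probe(fixture_probe(), rois = "side",
                     hemispheres = "right")
  pair <- generate_capping_pair(fixture_cohort(1)[1, ], pr, cfg,
                                seed = 8, duration_s = 30)
  u1 <- vapply(pair$fast$channels$channel, function(c)
    uncorrected_signal_mean(pair$fast, c), numeric(1))
  u2 <- vapply(pair$proper$channels$channel, function(c)
    uncorrected_signal_mean(pair$proper, c), numeric(1))
  expect_equal(u1, u2, tolerance = 1e-3)  # same effects, new noise only
})

test_that("auto-scaled source power divorces the two signal means", {
  cfg <- fixture_config()
  cfg$source_power_policy <- "auto-scaled"
  pr <- fixture_probe()
  ppl <- fixture_cohort(3)
  rec <- generate_recording(ppl[2, ], pr, 20, config = cfg, seed = 12)
  expect_true(any(rec$source_power_pct < 100))
  q <- suppressWarnings(channel_quality(rec, sci = FALSE))
  fixed <- fixture_config()
  rec_f <- generate_recording(ppl[2, ], pr, 20, config = fixed, seed = 12)
  qf <- suppressWarnings(channel_quality(rec_f, sci = FALSE))
  # Power correction recovers the same corrected mean either way (up to
  # the constant log10(100/reference-drive) offset of the auto mode),
  # while the uncorrected means differ on attenuated channels.
  expect_equal(q$csm - log10(100 / 25), qf$csm, tolerance = 0.05)
  expect_gt(max(abs(q$usm - qf$usm) / pmax(qf$usm, 1e-12)), 0.5)
})
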