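test_that("scale labels encode to their documented codes", {
  expect_equal(encode_scales("Kinky", "hair_type"), 4L)
  expect_equal(encode_scales("No Hair", "hair_type"), 0L)
  expect_equal(encode_scales(c("Blonde", "Red / Black"), "hair_color"),
               c(2L, 4L))
  expect_equal(encode_scales("Coarse", "hair_texture"), 3L)
  expect_equal(encode_scales(c("I", "III", "V", "VI"), "fitzpatrick"),
               c(1L, 2L, 3L, 3L))
  expect_error(encode_scales("Purple", "hair_color"), "unknown")
})

test_that("metric normalisation maps the range onto [0, 1] with clipping", {
  expect_equal(normalize_metric(42, 42, 88), 0)
  expect_equal(normalize_metric(88, 42, 88), 1)
  expect_equal(normalize_metric(65, 42, 88), 0.5)
  expect_warning(v <- normalize_metric(100, 42, 88), "clipped")
  expect_equal(v, 1)
  expect_error(normalize_metric(1, 5, 5), "exceed")
})

test_that("the combined metric matches an independent recomputation", {
  expect_equal(combined_hair_skin_metric(42, 0, 0, 4.7), 0)
  expect_equal(combined_hair_skin_metric(88, 4, 4, 90), 1)
  # Spreadsheet-style recomputation of the mid case.
  by_hand <- mean(c((65 - 42) / (88 - 42), 2 / 4, 3 / 4,
                    (25.3 - 4.7) / (90 - 4.7)))
  got <- combined_hair_skin_metric(65, 2, 3, 25.3)
  expect_equal(got, by_hand, tolerance = 1e-12)
  expect_equal(got, 0.49788, tolerance = 1e-5)
})

test_that("the combined metric is monotone and symmetric in its inputs", {
  set.seed(4)
  for (i in 1:50) {
    th <- runif(1, 42, 88); ty <- sample(0:4, 1)
    co <- sample(0:4, 1); pg <- runif(1, 4.7, 90)
    base <- combined_hair_skin_metric(th, ty, co, pg)
    expect_gte(combined_hair_skin_metric(min(th + 5, 88), ty, co, pg), base)
    expect_gte(combined_hair_skin_metric(th, min(ty + 1, 4), co, pg), base)
    expect_gte(combined_hair_skin_metric(th, ty, min(co + 1, 4), pg), base)
    expect_gte(combined_hair_skin_metric(th, ty, co, min(pg + 5, 90)), base)
  }
  # Equal weights: swapping the two 0-4 scales leaves the metric fixed.
  expect_equal(combined_hair_skin_metric(60, 1, 3, 30),
               combined_hair_skin_metric(60, 3, 1, 30))
})

test_that("group assignment partitions [0, 1] into the five bins", {
  expect_equal(assign_group(0.5), 3L)     # [0.45, 0.60)
  expect_equal(assign_group(1.0), 5L)     # closed upper bin
  expect_equal(assign_group(0.30), 2L)    # half-open on the right
  expect_equal(assign_group(0.10), 1L)    # below 0.15 folds into group 1
  expect_equal(assign_group(c(0.15, 0.45, 0.60, 0.75)), c(1L, 3L, 4L, 5L))
  set.seed(9)
  v <- runif(500)
  g <- assign_group(v)
  expect_true(all(g %in% 1:5))
  expect_equal(length(g), length(v))      # every value maps to one group
  expect_error(assign_group(1.2), "\\[0, 1\\]")
})

test_that("participant_metrics averages side and back thickness", {
  ppl <- fixture_cohort(10)
  th <- (ppl$side_avg_shaft_thickness + ppl$back_avg_shaft_thickness) / 2
  expect_equal(ppl$combined_metric,
               combined_hair_skin_metric(th, ppl$hair_type,
                                         ppl$hair_color,
                                         ppl$skin_pigmentation))
  expect_equal(ppl$metric_group, assign_group(ppl$combined_metric))
})
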