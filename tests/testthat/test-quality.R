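test_that("uncorrected signal mean averages time then wavelengths", {
  n <- 200
  rec <- manual_recording(list(matrix(0.33, n, 2)))
  expect_equal(uncorrected_signal_mean(rec, 1), 0.33)

  rec2 <- manual_recording(list(cbind(rep(0.2, n), rep(0.4, n))))
  expect_equal(uncorrected_signal_mean(rec2, 1), 0.3)

  set.seed(5)
  tr <- cbind(runif(n, 0.1, 0.5), runif(n, 0.1, 0.5))
  rec3 <- manual_recording(list(tr))
  brute <- 0
  for (w in 1:2) {
    s <- 0
    for (k in seq_len(n)) s <- s + tr[k, w]
    brute <- brute + s / n
  }
  brute <- brute / 2
  expect_equal(uncorrected_signal_mean(rec3, 1), brute, tolerance = 1e-12)
  expect_error(uncorrected_signal_mean(rec3, 99), "unknown channel")
})

test_that("corrected signal mean applies the power correction and log", {
  n <- 100
  rec <- manual_recording(list(matrix(0.5, n, 2)),
                          power = matrix(50, 1, 2))
  expect_equal(corrected_signal_mean(rec, 1), 0)  # log10(0.5/50*100)

  rec2 <- manual_recording(list(matrix(0.17, n, 2)))
  expect_equal(corrected_signal_mean(rec2, 1), log10(0.17),
               tolerance = 1e-12)
  expect_equal(round(corrected_signal_mean(rec2, 1), 4), -0.7696)

  rec3 <- manual_recording(list(matrix(1, n, 2)))
  expect_equal(corrected_signal_mean(rec3, 1), 0)

  # Invariance: doubling intensity and power together changes nothing.
  set.seed(8)
  tr <- cbind(runif(n, 0.2, 0.4), runif(n, 0.2, 0.4))
  a <- corrected_signal_mean(
    manual_recording(list(tr), power = matrix(50, 1, 2)), 1)
  b <- corrected_signal_mean(
    manual_recording(list(2 * tr), power = matrix(100, 1, 2)), 1)
  expect_equal(a, b, tolerance = 1e-12)

  neg <- manual_recording(list(matrix(-0.1, n, 2)))
  expect_warning(v <- corrected_signal_mean(neg, 1), "non-positive")
  expect_true(is.na(v))
})

test_that("SCI reaches the degenerate extremes and rejects short traces", {
  n <- 1224  # 2 minutes at 10.2 Hz
  t <- (0:(n - 1)) / 10.2
  cardiac <- sin(2 * pi * 1.1 * t)
  rec <- manual_recording(list(cbind(0.3 + 0.003 * cardiac,
                                     0.2 + 0.002 * cardiac)))
  expect_equal(scalp_coupling_index(rec, 1), 1, tolerance = 1e-9)

  rec_neg <- manual_recording(list(cbind(0.3 + 0.003 * cardiac,
                                         0.2 - 0.002 * cardiac)))
  expect_equal(scalp_coupling_index(rec_neg, 1), -1, tolerance = 1e-9)

  short <- manual_recording(list(matrix(0.3, 50, 2)))
  expect_error(scalp_coupling_index(short, 1), "10 s")

  flat <- manual_recording(list(matrix(0.3, n, 2)))
  expect_warning(v <- scalp_coupling_index(flat, 1), "zero-variance")
  expect_true(is.na(v))
})

test_that("SCI is invariant to positive per-wavelength affine scaling", {
  n <- 1836
  set.seed(21)
  base <- cbind(0.3 * (1 + 0.01 * rnorm(n)), 0.2 * (1 + 0.01 * rnorm(n)))
  rec <- manual_recording(list(base))
  scaled <- manual_recording(list(cbind(3.7 * base[, 1] + 0.5,
                                        0.04 * base[, 2] - 0.2)))
  expect_equal(scalp_coupling_index(rec, 1),
               scalp_coupling_index(scaled, 1), tolerance = 1e-9)
})

test_that("Fisher z matches atanh with clipping at perfect correlation", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.95), 4), 1.8318)
  expect_equal(fisher_z(-0.95), -fisher_z(0.95))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("SNR pruning excludes strictly below threshold", {
  n <- 4000
  set.seed(3)
  # Construct traces with exact sample mean/SD ratios via standardisation.
  make_snr <- function(target) {
    z <- rnorm(n)
    z <- (z - mean(z)) / sd(z)
    cbind(target + z, target + z)  # mean = target, sd = 1
  }
  rec <- manual_recording(list(make_snr(5), make_snr(4.999),
                               matrix(7, n, 2)))
  q <- suppressWarnings(channel_quality(rec, sci = FALSE))
  expect_equal(q$snr[1], 5, tolerance = 1e-9)
  expect_true(q$pass_snr[1])                   # boundary retained
  expect_false(q$pass_snr[2])                  # 4.999 excluded
  expect_equal(q$snr[3], Inf)                  # constant trace
  expect_true(q$pass_snr[3])
  kept <- prune_by_snr(q)
  expect_setequal(kept$channel, c(1, 3))
})

test_that("compare_runs reports percent increase and paired significance", {
  set.seed(10)
  q1 <- tibble::tibble(participant = "p1", channel = 1:50, roi = "side",
                       sci = runif(50, 0.5, 0.9))
  q2 <- q1
  same <- compare_runs(q1, q2, "sci")
  expect_equal(same$percent_increase, 0)
  expect_equal(same$p_paired_t, 1)

  q3 <- q1
  q3$sci <- q1$sci + 0.1
  shift <- compare_runs(q1, q3, "sci")
  expect_lt(shift$p_paired_t, 1e-6)
  expect_gt(shift$percent_increase, 0)

  expect_error(compare_runs(q1, q2[-1, ], "sci"), "different channel sets")
})
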