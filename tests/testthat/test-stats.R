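test_that("equal-width bins cover the range half-open on the right", {
  x <- c(0, 0.5, 1.0, 2.5, 4)
  b <- equal_width_bins(x)
  expect_equal(b, c(1L, 1L, 2L, 3L, 4L))
  expect_error(equal_width_bins(rep(2, 5)), "constant")
  expect_error(equal_width_bins(c(1, NA)), "finite")
})

test_that("Mann-Whitney p-values match exact combinatorics", {
  # Identical groups: no evidence, p = 1.
  y <- rep(c(1, 2, 3, 4), 2)
  bins <- rep(c(1, 4), each = 4)
  expect_equal(mann_whitney_first_last(y, bins)$p, 1)

  # Complete separation, n1 = n2 = 10: exact two-sided p = 2/C(20,10).
  y2 <- c(1:10, 101:110)
  bins2 <- rep(c(1, 4), each = 10)
  res <- mann_whitney_first_last(y2, bins2)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$U %in% c(0, 100))

  expect_error(mann_whitney_first_last(numeric(0), integer(0)),
               "non-empty")
})

test_that("Mann-Whitney agrees with a permutation oracle at small n", {
  set.seed(61)
  for (n1 in c(3, 5, 8)) {
    for (n2 in c(3, 6, 8)) {
      g1 <- rnorm(n1)
      g2 <- rnorm(n2, mean = 0.8)
      got <- mann_whitney_first_last(c(g1, g2),
                                     rep(c(1, 2), c(n1, n2)))$p
      want <- permutation_mw_p(g1, g2)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(as.numeric(bh_adjust(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  expect_equal(as.numeric(bh_adjust(0.037)), 0.037)
  expect_equal(as.numeric(bh_adjust(rep(1, 5))), rep(1, 5))
  set.seed(2)
  p <- runif(30)
  adj <- as.numeric(bh_adjust(p))
  expect_true(all(adj >= p))                       # never smaller than raw
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in raw p
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman correlation handles monotone, tied and small cases", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  res <- spearman(1:5, c(2, 1, 4, 3, 5))
  # By hand: squared rank differences 1,1,1,1,0 -> rho = 1 - 6*4/120.
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24))
  tt <- res$rho * sqrt(3 / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(-abs(tt), 3), tolerance = 1e-12)
  expect_warning(out <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman(1:2, 1:2), "n >= 3")
})

test_that("the robust line resists a gross outlier that breaks OLS", {
  x <- 1:20
  y <- 2 * x + 1
  fit <- robust_linfit(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)

  y_out <- y
  y_out[20] <- y[20] + 200
  rob <- robust_linfit(x, y_out)
  ols <- coef(lm(y_out ~ x))
  expect_lt(abs(rob$slope - 2), 0.05)
  expect_gt(abs(ols[2] - 2), 0.05)  # OLS is dragged by the outlier

  flat <- robust_linfit(x, rep(3, 20))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
})

test_that("the robust line agrees with an independent bisquare fit", {
  skip_if_not_installed("MASS")
  set.seed(14)
  x <- runif(60, 0, 10)
  y <- 1.5 * x - 2 + rnorm(60, sd = 0.5)
  y[c(7, 33)] <- y[c(7, 33)] + 15
  ours <- robust_linfit(x, y)
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-2)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 5e-2)
})

test_that("fold change applies the unlog and sign rule", {
  # Endpoints exactly 1 and 10 on the unlogged scale.
  x <- rep(c(0, 1), each = 100)
  up <- fold_change(list(slope = 1, intercept = 0), x)
  expect_equal(up$L, 1)
  expect_equal(up$U, 10)
  expect_equal(up$fold_change, 10)

  down <- fold_change(list(slope = -1, intercept = 1), x)
  expect_equal(down$L, 10)
  expect_equal(down$U, 1)
  expect_equal(down$fold_change, -10)

  # Sign rule: the fold change always shares its sign with U - L.
  set.seed(3)
  for (i in 1:25) {
    f <- list(slope = rnorm(1), intercept = rnorm(1))
    xx <- rnorm(50)
    fc <- fold_change(f, xx)
    expect_gte(abs(fc$fold_change), 1)
    expect_equal(sign(fc$fold_change) >= 0, fc$U >= fc$L)
  }
})

test_that("multicollinearity screening keeps the priority predictor", {
  set.seed(19)
  n <- 200
  z <- matrix(rnorm(3 * n), n)
  a <- z[, 1]
  b <- 0.9 * scale(a)[, 1] + sqrt(1 - 0.81) * scale(z[, 2])[, 1]
  X <- cbind(a = a, b = b, c = z[, 3])
  expect_setequal(multicollinearity_screen(X, priority = c("a", "b", "c")),
                  c("a", "c"))

  orth <- cbind(a = z[, 1], b = z[, 2], c = z[, 3])
  expect_setequal(multicollinearity_screen(orth), c("a", "b", "c"))

  # Chain a~b strong, b~c moderate: dropping b breaks the chain, c stays.
  resid_std <- function(v, on) scale(resid(lm(v ~ on)))[, 1]
  b2 <- 0.8 * scale(a)[, 1] + sqrt(1 - 0.64) * resid_std(z[, 2], a)
  c2 <- 0.6 * scale(b2)[, 1] + sqrt(1 - 0.36) * resid_std(z[, 3], cbind(a, b2))
  X2 <- cbind(a = a, b = b2, c = c2)
  expect_setequal(multicollinearity_screen(X2, priority = c("a", "b", "c")),
                  c("a", "c"))
})

test_that("VIF matches the closed form and an independent implementation", {
  set.seed(23)
  n <- 300
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(resid(lm(rnorm(n) ~ z1)))[, 1]  # exactly orthogonal to z1
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2        # empirical r = 0.8 exactly
  v <- vif(cbind(a = z1, b = x2))
  expect_equal(as.numeric(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  orth <- vif(cbind(a = z1, b = z2))
  expect_equal(as.numeric(orth), c(1, 1), tolerance = 1e-9)

  dup <- suppressWarnings(vif(cbind(a = z1, b = z1)))
  expect_true(all(dup == Inf))

  skip_if_not_installed("car")
  X <- matrix(rnorm(3 * n), n)
  X[, 2] <- X[, 2] + 0.5 * X[, 1]
  colnames(X) <- c("p1", "p2", "p3")
  y <- rnorm(n)
  ref <- car::vif(lm(y ~ X[, 1] + X[, 2] + X[, 3]))
  expect_equal(as.numeric(vif(X)), unname(ref), tolerance = 1e-8)
})

test_that("robust multiple regression recovers a noiseless model exactly", {
  set.seed(31)
  X <- matrix(rnorm(50 * 3), 50)
  colnames(X) <- c("p1", "p2", "p3")
  y <- 2 + 1.5 * X[, 1] - 0.7 * X[, 2] + 0 * X[, 3]
  # A perfect fit makes f^2 degenerate; that is flagged, not silent.
  expect_warning(cohens_f2(X, y, "p1"), "unstable")
  rep_tab <- suppressWarnings(robust_multiple_regression(X, y))
  expect_equal(rep_tab$estimate, c(1.5, -0.7, 0), tolerance = 1e-8)
  expect_true(all(rep_tab$vif >= 1 - 1e-9))
})

test_that("robust regression estimates are unbiased over replicates", {
  set.seed(37)
  beta <- c(p1 = 1.2, p2 = -0.8, p3 = 0.5)
  est <- replicate(200, {
    X <- matrix(rnorm(115 * 3), 115)
    colnames(X) <- names(beta)
    y <- 1 + X %*% beta + rnorm(115)
    robust_multiple_regression(X, y)$estimate
  })
  bias <- rowMeans(est) - beta
  expect_true(all(abs(bias) < 0.05 * abs(beta)))
})

test_that("Cohen's f2 follows the partial-R-squared closed form", {
  set.seed(41)
  n <- 400
  X <- matrix(rnorm(n * 3), n)
  colnames(X) <- c("p1", "p2", "p3")
  y <- 0.8 * X[, 1] + 0.3 * X[, 2] + rnorm(n)
  tab <- robust_multiple_regression(X, y)
  # Closed form recomputed through the public API: f2 must equal
  # (R2_full - R2_reduced) / (1 - R2_full) with both R2s from the
  # robust fits.
  r2_full <- attr(tab, "r_squared")
  for (j in 1:3) {
    r2_red <- attr(robust_multiple_regression(X[, -j, drop = FALSE], y),
                   "r_squared")
    expect_equal(unname(tab$f2[j]),
                 max(0, (r2_full - r2_red) / (1 - r2_full)),
                 tolerance = 1e-10)
  }
  # Effect ordering matches the generating model; the null predictor
  # sits below the "small" band.
  expect_true(tab$f2[1] > tab$f2[2])
  expect_true(tab$f2[2] > tab$f2[3])
  expect_lt(unname(tab$f2[3]), 0.02)
  expect_true(all(tab$f2 >= 0))
  expect_equal(attr(tab, "f2_bands"),
               c(small = 0.02, medium = 0.15, large = 0.35))
})
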