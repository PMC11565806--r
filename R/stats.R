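#' Equal-width bins
#'
#' Divides the range of `x` into `k` equal-width intervals between its
#' minimum and maximum (half-open on the right except the last). Used for
#' violin-plot visualisation; correlation and regression analyses keep
#' the variables continuous.
#'
#' @param x Finite numeric values with `max > min`.
#' @param k Number of bins (default 4).
#' @return Integer bin ids 1..k.
#' @export
equal_width_bins <- function(x, k = 4) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (max(x) <= min(x)) stop("x is constant; bins are undefined")
  edges <- seq(min(x), max(x), length.out = k + 1)
  findInterval(x, edges, rightmost.closed = TRUE)
}

#' Mann-Whitney U test between the first and last bins
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the response
#' values in the lowest and highest bins. The p-value is exact when both
#' groups have at most 20 observations and no ties occur, and uses the
#' normal approximation with tie correction otherwise.
#'
#' @param y Response values.
#' @param bins Bin ids from [equal_width_bins()] (or any grouping).
#' @return A list with `U` (the rank-sum statistic of the first group)
#'   and `p`.
#' @export
mann_whitney_first_last <- function(y, bins) {
  if (length(y) == 0) stop("first and last bins must be non-empty")
  g1 <- y[bins == min(bins)]
  g2 <- y[bins == max(bins)]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("first and last bins must be non-empty")
  }
  ties <- any(duplicated(c(g1, g2)))
  use_exact <- length(g1) <= 20 && length(g2) <= 20 && !ties
  ht <- suppressWarnings(
    wilcox.test(g1, g2, exact = use_exact, correct = !use_exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at
#' 1). The study's significance threshold after adjustment is 0.01.
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @param alpha Significance threshold attached to the result as the
#'   attribute `alpha` (default 0.01).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals, alpha = 0.01) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- p.adjust(pvals, method = "BH")
  attr(out, "alpha") <- alpha
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return A list with `rho` and `p`; constant input yields `NA` with a
#'   warning.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), n - 2))
}

# Tukey bisquare weights for standardised residuals u = r / (c * s).
bisquare_weights <- function(res, scale, c = 4.685) {
  u <- res / (c * scale)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

# Iteratively reweighted least squares with bisquare weights.
# X includes the intercept column. Scale is re-estimated each iteration
# as median(|res|)/0.6745.
irls_fit <- function(X, y, c = 4.685, tol = 1e-8, max_iter = 50) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop("robust fit needs n > p + 1")
  qrx <- qr(X)
  if (qrx$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, y)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    res <- as.numeric(y - X %*% beta)
    s <- median(abs(res)) / 0.6745
    if (s < 1e-12 * max(1, median(abs(y)))) {
      converged <- TRUE
      w <- rep(1, n)
      break
    }
    w <- bisquare_weights(res, s, c)
    if (sum(w > 0) <= p) w <- pmax(w, 1e-6)  # guard against mass rejection
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta)) /
      max(1, max(abs(beta)))
    beta <- fit$coefficients
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  res <- as.numeric(y - X %*% beta)
  s <- median(abs(res)) / 0.6745
  if (s < 1e-12 * max(1, median(abs(y)))) s <- 0
  # Asymptotic covariance of the M-estimate:
  # [sum(psi^2)/(n-p)] / [mean(psi')]^2 * (X'X)^-1.
  if (s > 0) {
    u <- res / (c * s)
    psi <- ifelse(abs(u) < 1, res * (1 - u^2)^2, 0)
    psip <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    kappa2 <- (sum(psi^2) / (n - p)) / mean(psip)^2
  } else {
    kappa2 <- 0
  }
  covb <- kappa2 * chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(covb), 0))
  # Robust R^2 from weighted sums of squares at the converged weights.
  wm <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * res^2) / sum(w * (y - wm)^2)
  list(beta = beta, se = se, weights = w, scale = s, r_squared = r2,
       converged = converged, iterations = iter, df = n - p)
}

#' Robust simple linear regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685), converged to 1e-8 or at most 50 iterations,
#' minimising the influence of outliers on the fitted line.
#'
#' @param x,y Numeric vectors, `n >= 3`, non-constant `x`.
#' @return A list with `slope`, `intercept`, `converged` and
#'   `iterations`; non-convergence is flagged (last iterate returned).
#' @examples
#' robust_linfit(1:10, 2 * (1:10) + 1)[c("slope", "intercept")]
#' @export
robust_linfit <- function(x, y) {
  if (length(x) < 3) stop("robust fit requires n >= 3")
  if (sd(x) == 0) stop("x is constant")
  fit <- irls_fit(cbind(1, x), y)
  if (!fit$converged) {
    warning("robust fit did not converge within 50 iterations")
  }
  list(slope = unname(fit$beta[2]), intercept = unname(fit$beta[1]),
       converged = fit$converged, iterations = fit$iterations)
}

#' Percentile fold change of a log10-scale fit
#'
#' Evaluates a robust fit of a log10-scale response at the 1st and 99th
#' percentiles of the predictor (linear interpolation between order
#' statistics), transforms both endpoints back to the original scale
#' (`10^`), and applies the sign rule: the fold change is `U / L` when
#' the upper-percentile prediction `U` is at least the lower-percentile
#' prediction `L`, and `-L / U` otherwise, so its sign tracks the
#' direction of change and its magnitude is always at least 1.
#'
#' @param fit A list with `slope` and `intercept` on the log10 scale
#'   (e.g. from [robust_linfit()]).
#' @param x Predictor values whose 1st/99th percentiles define the
#'   endpoints.
#' @param probs Percentile pair (default `c(0.01, 0.99)`).
#' @return A list with `L`, `U`, `fold_change`, `slope`, `intercept`.
#' @export
fold_change <- function(fit, x, probs = c(0.01, 0.99)) {
  q <- quantile(x, probs, names = FALSE, type = 7)
  L <- 10^(fit$intercept + fit$slope * q[1])
  U <- 10^(fit$intercept + fit$slope * q[2])
  if (!is.finite(L) || !is.finite(U)) stop("non-finite fold-change endpoint")
  fc <- if (U >= L) U / L else -L / U
  list(L = L, U = U, fold_change = fc,
       slope = fit$slope, intercept = fit$intercept)
}

#' Screen predictors for multicollinearity
#'
#' Examines all pairwise Pearson correlations among predictors and, for
#' every pair exceeding the threshold in absolute value, keeps only the
#' higher-priority predictor. Pairs are processed in descending `|r|`
#' and correlations are re-checked among survivors after each drop, which
#' makes the rule deterministic for correlation chains.
#'
#' @param X Numeric matrix or data frame of predictors (>= 2 columns).
#' @param r_threshold Absolute-correlation threshold (default 0.5).
#' @param priority Column names in decreasing priority (default: column
#'   order; the study prioritises the more objective, interpretable
#'   metric, e.g. melanin index over Fitzpatrick type).
#' @return Character vector of retained predictor names.
#' @export
multicollinearity_screen <- function(X, r_threshold = 0.5,
                                     priority = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(priority)) priority <- colnames(X)
  retained <- colnames(X)
  repeat {
    if (length(retained) < 2) break
    cm <- abs(cor(X[, retained, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- retained[idx]
    drop <- pair[which.max(match(pair, priority))]
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing
#' predictor `j` on the remaining predictors. Values below 5 indicate low
#' multicollinearity, 5-10 moderate, above 10 problematic; the bands are
#' attached as the attribute `bands`. Rank-deficient designs yield `Inf`
#' for the affected predictors.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @return Named numeric vector of VIFs (all >= 1 up to rounding).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (nrow(X) <= p + 1) stop("vif needs n > p + 1")
  if (p == 1) {
    out <- 1
    names(out) <- colnames(X)
    attr(out, "bands") <- c(low = 5, moderate = 10)
    return(out)
  }
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "bands") <- c(low = 5, moderate = 10)
  out
}

#' Robust multiple regression report
#'
#' Fits the response on the (screened) predictors by iteratively
#' reweighted least squares with bisquare weights (the same weight
#' function and tuning as [robust_linfit()]), and reports for each
#' predictor the estimate, its standard error from the robust asymptotic
#' covariance, the t statistic, the two-sided p-value on `n - p - 1`
#' degrees of freedom, Cohen's f-squared from the robust R-squared
#' analogue (weighted sums of squares at the converged weights), and the
#' variance inflation factor. Cohen's guidelines read f^2 >= 0.02 / 0.15
#' / 0.35 as small / medium / large.
#'
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param y Response.
#' @return A tibble with one row per predictor: `predictor`, `estimate`,
#'   `se`, `tstat`, `pvalue`, `f2`, `vif`; the model's robust R-squared
#'   is the attribute `r_squared` and the f^2 bands the attribute
#'   `f2_bands`.
#' @export
robust_multiple_regression <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- irls_fit(Xd, y)
  if (!fit$converged) {
    warning("robust regression did not converge within 50 iterations")
  }
  keep <- seq_len(ncol(X)) + 1L
  f2 <- vapply(colnames(X), function(nm)
    cohens_f2(X, y, nm, full_fit = fit), numeric(1))
  out <- tibble::tibble(
    predictor = colnames(X),
    estimate = unname(fit$beta[keep]),
    se = unname(fit$se[keep]),
    tstat = unname(fit$beta[keep] / fit$se[keep]),
    f2 = f2,
    vif = unname(vif(X))
  )
  out$pvalue <- 2 * pt(-abs(out$tstat), fit$df)
  out <- out[, c("predictor", "estimate", "se", "tstat", "pvalue", "f2",
                 "vif")]
  attr(out, "r_squared") <- fit$r_squared
  attr(out, "f2_bands") <- c(small = 0.02, medium = 0.15, large = 0.35)
  out
}

#' Cohen's f-squared for one predictor
#'
#' Partial effect size
#' `f^2 = (R2_full - R2_without_j) / (1 - R2_full)`, with both
#' R-squareds taken from the robust fit's weighted analogue, floored at
#' zero. An essentially perfect full fit (`R2 = 1`) makes the ratio
#' unstable and is flagged.
#'
#' @param X Predictor matrix, `y` response, `predictor` the column to
#'   assess.
#' @param y Response.
#' @param predictor Column name in `X`.
#' @param full_fit Optional precomputed full-model fit (internal).
#' @return Non-negative f-squared.
#' @export
cohens_f2 <- function(X, y, predictor, full_fit = NULL) {
  X <- as.matrix(X)
  if (!predictor %in% colnames(X)) stop("unknown predictor: ", predictor)
  if (is.null(full_fit)) full_fit <- irls_fit(cbind(1, X), y)
  r2_full <- full_fit$r_squared
  if (r2_full >= 1 - 1e-10) {
    warning("full-model R^2 is 1; f^2 is unstable")
    return(Inf)
  }
  rest <- setdiff(colnames(X), predictor)
  r2_red <- if (length(rest) == 0) 0 else
    irls_fit(cbind(1, X[, rest, drop = FALSE]), y)$r_squared
  max(0, (r2_full - r2_red) / (1 - r2_full))
}
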