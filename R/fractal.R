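#' Default analysis scales for fluctuation analysis
#'
#' Twenty log-spaced integer scales spanning 10 to 600 minutes, shared by
#' [dfa()] and [mfdfa()]. The short-scale exponent is fitted over 10-90 min
#' and the long-scale exponent over 120-600 min.
#'
#' @param n_scales Number of scales.
#' @param min_scale,max_scale Scale range in minutes.
#' @return Integer vector of scales.
#' @export
dfa_scales <- function(n_scales = 20, min_scale = 10, max_scale = 600) {
  unique(round(exp(seq(log(min_scale), log(max_scale), length.out = n_scales))))
}

# polynomial detrending basis at a given window size, cached because the
# scale grid is fixed across thousands of calls; residuals are computed as
# Y - X (X'X)^-1 X' Y, which is O(order * n) per window instead of the
# O(n^2) of an explicit residual-maker matrix
.detrend_basis <- function(n, order) {
  key <- paste0("basis_", n, "_", order)
  B <- .nof1_cache[[key]]
  if (is.null(B)) {
    tt <- seq_len(n) / n
    X <- cbind(1, stats::poly(tt, degree = order, raw = TRUE))
    B <- list(X = X, A = solve(crossprod(X), t(X)))
    .nof1_cache[[key]] <- B
  }
  B
}

# Per-scale squared window fluctuations of the integrated profile.
# `x` may contain NA (tolerated gaps); increments at missing minutes
# contribute nothing to the profile, and any window touching a missing
# minute is excluded from the fluctuation average.  Windows are
# non-overlapping and taken in a forward and a reverse pass so trailing
# remainder data are used.
.window_fluctuations <- function(x, scales, detrend_order = 2) {
  miss <- is.na(x)
  y <- x - mean(x, na.rm = TRUE)
  y[miss] <- 0
  pf <- cumsum(y)
  prof <- list(pf, rev(pf))
  cmiss <- list(c(0, cumsum(miss)), c(0, cumsum(rev(miss))))
  N <- length(y)
  # numerical-zero threshold for squared residuals, relative to the profile
  # scale: exactly detrendable windows leave O(1e-12) rounding residue
  zero_tol <- (1e-10 * max(abs(pf), 1))^2
  out <- lapply(scales, function(n) {
    K <- N %/% n
    if (K < 1L) return(numeric(0))
    B <- .detrend_basis(n, detrend_order)
    f2 <- numeric(0)
    for (pass in 1:2) {
      p <- prof[[pass]]
      cm <- cmiss[[pass]]
      ends <- seq_len(K) * n
      bad <- (cm[ends + 1L] - cm[ends - n + 1L]) > 0
      if (all(bad)) next
      Y <- matrix(p[seq_len(K * n)], nrow = n)[, !bad, drop = FALSE]
      R <- Y - B$X %*% (B$A %*% Y)
      f2 <- c(f2, colMeans(R^2))
    }
    f2
  })
  attr(out, "zero_tol") <- zero_tol
  out
}

#' Least-squares scaling exponent of a fluctuation curve
#'
#' Ordinary least-squares slope of `log F(n)` against `log n`, restricted to
#' scales inside `range`. At least three usable scales with positive `F`
#' are required; otherwise `NA` is returned.
#'
#' @param n Scales (minutes).
#' @param Fn Fluctuation values at those scales.
#' @param range Length-2 numeric, inclusive scale range for the fit.
#' @return The fitted exponent, or `NA_real_`.
#' @export
fit_exponent <- function(n, Fn, range) {
  keep <- n >= range[1] & n <= range[2] & is.finite(Fn) & Fn > 0
  if (sum(keep) < 3L) return(NA_real_)
  ln <- log(n[keep]); lf <- log(Fn[keep])
  sum((ln - mean(ln)) * (lf - mean(lf))) / sum((ln - mean(ln))^2)
}

#' Detrended fluctuation analysis of minute-level activity counts
#'
#' Integrates the mean-centered counts, detrends non-overlapping windows at
#' each scale with an order-`detrend_order` polynomial (forward and reverse
#' passes averaged), and fits two scaling exponents: `alpha1` over 10-90 min
#' and `alpha2` over 120-600 min. An exponent of 0.5 indicates uncorrelated
#' fluctuations; values near 1 indicate the long-range correlations typical
#' of healthy motor-activity regulation.
#'
#' Missing values (`NA`) are tolerated small gaps: windows touching them are
#' dropped from the fluctuation average rather than imputed.
#'
#' @param x Numeric vector of minute counts spanning at least two full days
#'   (2880 points).
#' @param scales Analysis scales; see [dfa_scales()].
#' @param detrend_order Polynomial detrending order.
#' @param alpha1_range,alpha2_range Fit ranges in minutes.
#' @return An object of class `dfa_result`: list with `scales`, `fluctuation`
#'   `F(n)`, `alpha1`, `alpha2`, per-regime fit R^2 and a `degenerate` flag
#'   (all-zero residuals at some fitted scale).
#' @export
dfa <- function(x, scales = dfa_scales(), detrend_order = 2,
                alpha1_range = c(10, 90), alpha2_range = c(120, 600),
                .f2 = NULL) {
  if (length(x) < 2L * 1440L)
    stop("segment shorter than 2 days (", length(x), " < 2880 minutes)")
  f2 <- if (is.null(.f2)) .window_fluctuations(x, scales, detrend_order) else .f2
  zero_tol <- attr(f2, "zero_tol")
  if (is.null(zero_tol)) zero_tol <- 0
  Fn <- vapply(f2, function(v) if (length(v)) sqrt(mean(v)) else NA_real_,
               numeric(1))
  in_fit <- (scales >= alpha1_range[1] & scales <= alpha1_range[2]) |
            (scales >= alpha2_range[1] & scales <= alpha2_range[2])
  degenerate <- any(is.finite(Fn[in_fit]) & Fn[in_fit]^2 <= zero_tol)
  a1 <- if (degenerate) NA_real_ else fit_exponent(scales, Fn, alpha1_range)
  a2 <- if (degenerate) NA_real_ else fit_exponent(scales, Fn, alpha2_range)
  r2 <- function(range) {
    keep <- scales >= range[1] & scales <= range[2] & is.finite(Fn) & Fn > 0
    if (sum(keep) < 3L) return(NA_real_)
    summary(lm(log(Fn[keep]) ~ log(scales[keep])))$r.squared
  }
  structure(list(scales = scales, fluctuation = Fn,
                 alpha1 = a1, alpha2 = a2,
                 fit_r2 = c(alpha1 = if (degenerate) NA_real_ else r2(alpha1_range),
                            alpha2 = if (degenerate) NA_real_ else r2(alpha2_range)),
                 degenerate = degenerate),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("<dfa_result> alpha1 =", round(x$alpha1, 3),
      " alpha2 =", round(x$alpha2, 3),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Multifractal detrended fluctuation analysis
#'
#' Extends [dfa()] to q-order moments of the window fluctuations:
#' `Fq(s) = (mean(F2(v,s)^(q/2)))^(1/q)` for `q != 0` and the logarithmic
#' average `exp(mean(log F2)/2)` at `q = 0`. The generalized Hurst exponent
#' `h(q)` is the log-log slope of `Fq(s)` per moment, and the multifractal
#' width `h(q_min) - h(q_max)` indexes the diversity of local scaling:
#' near zero for monofractal signals, large for multiplicative cascades.
#'
#' @inheritParams dfa
#' @param q_grid Moment orders; the default is -5 to 5 in steps of 0.1
#'   (101 values).
#' @param hurst_range Scale range for the `h(q)` fits.
#' @return An object of class `mfdfa_result`: list with `q`, `hurst` (`h(q)`),
#'   `width`, `scales` and the `fq` matrix (scales x moments).
#' @export
mfdfa <- function(x, q_grid = seq(-5, 5, by = 0.1), scales = dfa_scales(),
                  detrend_order = 2, hurst_range = c(10, 600), .f2 = NULL) {
  if (length(x) < 2L * 1440L)
    stop("segment shorter than 2 days (", length(x), " < 2880 minutes)")
  f2 <- if (is.null(.f2)) .window_fluctuations(x, scales, detrend_order) else .f2
  zero_tol <- attr(f2, "zero_tol")
  if (is.null(zero_tol)) zero_tol <- 0
  n_zero <- sum(vapply(f2, function(v) sum(v <= zero_tol), numeric(1)))
  if (n_zero > 0) message(n_zero, " zero-variance windows excluded from MFDFA")
  f2 <- lapply(f2, function(v) v[v > zero_tol])
  usable <- vapply(f2, length, integer(1)) > 0
  if (sum(usable) < 3L)
    return(structure(list(q = q_grid, hurst = rep(NA_real_, length(q_grid)),
                          width = NA_real_, scales = scales, fq = NULL),
                     class = "mfdfa_result"))
  fq <- vapply(q_grid, function(q) {
    vapply(f2, function(v) {
      if (!length(v)) return(NA_real_)
      if (abs(q) < 1e-12) exp(0.5 * mean(log(v)))
      else mean(v^(q / 2))^(1 / q)
    }, numeric(1))
  }, numeric(length(scales)))
  h <- apply(fq, 2, function(col) fit_exponent(scales, col, hurst_range))
  structure(list(q = q_grid, hurst = h,
                 width = h[1L] - h[length(h)],
                 scales = scales, fq = fq),
            class = "mfdfa_result")
}

#' @export
print.mfdfa_result <- function(x, ...) {
  cat("<mfdfa_result> width =", round(x$width, 3),
      " h(2) =", round(x$hurst[which.min(abs(x$q - 2))], 3), "\n")
  invisible(x)
}
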