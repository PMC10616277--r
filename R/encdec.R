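# ---- low-level LSTM machinery (base R, full-batch BPTT) ---------------------
#
# Gate layout in the 4H-wide pre-activation block: [input | forget | cell | output].
# All loops are over the (short) time axis; each step is a handful of
# (batch x hidden) matrix products, which BLAS handles quickly.

.sigm <- function(x) 1 / (1 + exp(-x))

.lstm_init <- function(input_dim, hidden) {
  s <- 1 / sqrt(hidden)
  ru <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
  mk <- function(d) {
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1     # forget-gate bias starts open
    list(Wx = ru(d, 4 * hidden), Wh = ru(hidden, 4 * hidden), b = b)
  }
  list(enc = mk(input_dim), dec = mk(input_dim),
       Wy = ru(hidden, input_dim), by = rep(0, input_dim))
}

.zeros_like <- function(p) rapply(p, function(m) m * 0, how = "replace")

.lstm_step <- function(w, Xt, Hprev, Cprev, hidden) {
  A <- Xt %*% w$Wx + Hprev %*% w$Wh
  A <- sweep(A, 2, w$b, "+")
  i <- .sigm(A[, 1:hidden, drop = FALSE])
  f <- .sigm(A[, (hidden + 1):(2 * hidden), drop = FALSE])
  g <- tanh(A[, (2 * hidden + 1):(3 * hidden), drop = FALSE])
  o <- .sigm(A[, (3 * hidden + 1):(4 * hidden), drop = FALSE])
  C <- f * Cprev + i * g
  tC <- tanh(C)
  list(H = o * tC, C = C, cache = list(X = Xt, Hprev = Hprev, Cprev = Cprev,
                                       i = i, f = f, g = g, o = o, tC = tC))
}

.lstm_step_back <- function(w, cache, dH, dCin, grad) {
  dC <- dCin + dH * cache$o * (1 - cache$tC^2)
  di <- dC * cache$g
  df <- dC * cache$Cprev
  dg <- dC * cache$i
  do <- dH * cache$tC
  dA <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do * cache$o * (1 - cache$o))
  grad$Wx <- grad$Wx + crossprod(cache$X, dA)
  grad$Wh <- grad$Wh + crossprod(cache$Hprev, dA)
  grad$b <- grad$b + colSums(dA)
  list(dX = dA %*% t(w$Wx), dHprev = dA %*% t(w$Wh), dCprev = dC * cache$f,
       grad = grad)
}

# forward pass over a batch of segments.
# X: array [T, B, D].  The decoder is conditioned on the encoder's final
# state and re-feeds its own previous prediction (teacher-free); it emits
# the sequence in reverse order, so Y[t, , ] reconstructs X[T + 1 - t, , ].
.encdec_forward <- function(p, X, hidden, keep_cache = FALSE) {
  Tlen <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  H <- matrix(0, B, hidden); C <- matrix(0, B, hidden)
  ecache <- if (keep_cache) vector("list", Tlen)
  for (t in seq_len(Tlen)) {
    st <- .lstm_step(p$enc, matrix(X[t, , ], B, D), H, C, hidden)
    H <- st$H; C <- st$C
    if (keep_cache) ecache[[t]] <- st$cache
  }
  Y <- array(0, dim = c(Tlen, B, D))
  dcache <- if (keep_cache) vector("list", Tlen)
  U <- matrix(0, B, D)
  for (t in seq_len(Tlen)) {
    st <- .lstm_step(p$dec, U, H, C, hidden)
    H <- st$H; C <- st$C
    yt <- H %*% p$Wy
    yt <- sweep(yt, 2, p$by, "+")
    Y[t, , ] <- yt
    if (keep_cache) dcache[[t]] <- c(st$cache, list(Hout = H))
    U <- yt
  }
  loss <- mean((Y - X[Tlen:1, , , drop = FALSE])^2)
  list(Y = Y, loss = loss, ecache = ecache, dcache = dcache)
}

.encdec_backward <- function(p, X, fwd, hidden) {
  Tlen <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  gr <- list(enc = .zeros_like(p$enc), dec = .zeros_like(p$dec),
             Wy = p$Wy * 0, by = p$by * 0)
  sc <- 2 / (Tlen * B * D)
  dH <- matrix(0, B, hidden); dC <- matrix(0, B, hidden)
  dU <- matrix(0, B, D)                    # grad into the re-fed prediction
  for (t in Tlen:1) {
    tgt <- matrix(X[Tlen + 1 - t, , ], B, D)
    dY <- sc * (matrix(fwd$Y[t, , ], B, D) - tgt) + dU
    Hout <- fwd$dcache[[t]]$Hout
    gr$Wy <- gr$Wy + crossprod(Hout, dY)
    gr$by <- gr$by + colSums(dY)
    dH <- dH + dY %*% t(p$Wy)
    bk <- .lstm_step_back(p$dec, fwd$dcache[[t]], dH, dC, gr$dec)
    gr$dec <- bk$grad
    dU <- bk$dX
    dH <- bk$dHprev; dC <- bk$dCprev
  }
  # state handoff: decoder's initial (H, C) is the encoder's final state
  for (t in length(fwd$ecache):1) {
    bk <- .lstm_step_back(p$enc, fwd$ecache[[t]], dH, dC, gr$enc)
    gr$enc <- bk$grad
    dH <- bk$dHprev; dC <- bk$dCprev
  }
  gr
}

.adam_update <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  flat_names <- names(st$m)
  for (nm in flat_names) {
    gi <- g[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gi
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gi^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, st = st)
}

# flatten nested parameter list for uniform Adam bookkeeping
.flatten_params <- function(p) {
  list(enc.Wx = p$enc$Wx, enc.Wh = p$enc$Wh, enc.b = p$enc$b,
       dec.Wx = p$dec$Wx, dec.Wh = p$dec$Wh, dec.b = p$dec$b,
       Wy = p$Wy, by = p$by)
}
.unflatten_params <- function(f) {
  list(enc = list(Wx = f$enc.Wx, Wh = f$enc.Wh, b = f$enc.b),
       dec = list(Wx = f$dec.Wx, Wh = f$dec.Wh, b = f$dec.b),
       Wy = f$Wy, by = f$by)
}

# ---- segments ----------------------------------------------------------------

#' Sliding 14-day segments of the daily feature series
#'
#' Cuts the daily multivariate feature series into overlapping windows at
#' daily stride, z-normalizes each feature with the supplied (training)
#' statistics and imputes missing values with zero *after* normalization,
#' so an imputed value equals the training mean.
#'
#' @param x Numeric matrix (days x features), or a [feature_table()] data
#'   frame whose `date` column is dropped.
#' @param window Segment length in days.
#' @param stride Step between consecutive segment starts, in days.
#' @param center,scale Per-feature normalization statistics. When `NULL`
#'   they are computed from `x` (training use); test segments must reuse the
#'   training statistics.
#' @param sd_floor Scale entries below this are replaced by 1 so constant
#'   features pass through unscaled.
#' @return An object of class `feature_segments`: list with `arr` (array
#'   `[window, n_segments, n_features]`), `starts` (first row of each
#'   segment), `center`, `scale`. When fewer than `window` days are
#'   available, `n_segments` is zero and a diagnostic message is emitted.
#' @export
make_segments <- function(x, window = 14, stride = 1,
                          center = NULL, scale = NULL, sd_floor = 1e-8) {
  x <- .as_feature_matrix(x)
  n <- nrow(x); D <- ncol(x)
  if (is.null(center)) center <- apply(x, 2, function(v) mean(v, na.rm = TRUE))
  if (is.null(scale)) scale <- apply(x, 2, function(v) sd(v, na.rm = TRUE))
  center[!is.finite(center)] <- 0
  scale[!is.finite(scale) | scale < sd_floor] <- 1
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  z[is.na(z)] <- 0
  starts <- if (n >= window) seq(1L, n - window + 1L, by = stride) else integer(0)
  if (!length(starts)) message("fewer than ", window, " days: no segments")
  arr <- array(0, dim = c(window, length(starts), D))
  for (b in seq_along(starts))
    arr[, b, ] <- z[starts[b]:(starts[b] + window - 1L), , drop = FALSE]
  structure(list(arr = arr, starts = starts, center = center, scale = scale),
            class = "feature_segments")
}

.as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), c("date", "patient_id")), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

# ---- the fitted model --------------------------------------------------------

#' Fit a per-patient LSTM encoder-decoder anomaly detector
#'
#' Trains a single-layer LSTM encoder-decoder to reconstruct 14-day
#' segments of the z-normalized daily feature series, using only
#' relapse-free data. The decoder is conditioned on the encoder's final
#' state and re-feeds its own predictions while emitting the segment in
#' reverse order. Training minimizes mean squared reconstruction error with
#' Adam (full batch, deterministic under `seed`), with early stopping on a
#' held-out trailing share of segments. The error vectors
#' `e = |x - x_hat|` of that held-out share fit the multivariate normal
#' error model used for Mahalanobis scoring (see [fit_error_model()]).
#'
#' @param x Training feature series: days x features matrix or
#'   [feature_table()] data frame (relapse-free days only).
#' @param hidden_size LSTM hidden units.
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed for weight initialization (training itself is
#'   deterministic).
#' @param window Segment length in days.
#' @param val_frac Trailing fraction of segments held out from weight
#'   fitting; supplies the early-stopping criterion and the error-model fit.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param ridge_cond Condition-number ceiling for the error covariance.
#' @param init Optional previous `encdec_ad` fit to warm-start from
#'   (continued training on grown data).
#' @return An object of class `encdec_ad` with elements `params`, `center`,
#'   `scale`, `error_model`, `history` (train/validation loss per epoch),
#'   `n_train_days`, and the fitting configuration.
#' @export
encdec_ad <- function(x, hidden_size = 32, epochs = 200, lr = 0.01, seed = 1,
                      window = 14, val_frac = 0.2, patience = 15,
                      ridge_cond = 1e8, init = NULL) {
  x <- .as_feature_matrix(x)
  D <- ncol(x)
  segs <- make_segments(x, window = window)
  nb <- length(segs$starts)
  if (nb < 1L) stop("need at least one ", window, "-day training segment")

  n_val <- if (nb >= 5L) max(1L, floor(val_frac * nb)) else 0L
  tr_idx <- seq_len(nb - n_val)
  va_idx <- if (n_val > 0L) (nb - n_val + 1L):nb else tr_idx
  Xtr <- segs$arr[, tr_idx, , drop = FALSE]
  Xva <- segs$arr[, va_idx, , drop = FALSE]

  set.seed(seed)
  p <- if (is.null(init)) .lstm_init(D, hidden_size) else init$params
  if (!is.null(init) && init$hidden_size != hidden_size)
    stop("warm start requires matching hidden size")
  fl <- .flatten_params(p)
  st <- list(m = .zeros_like(fl), v = .zeros_like(fl), t = 0)
  best <- list(loss = Inf, fl = fl)
  history <- matrix(NA_real_, epochs, 2, dimnames = list(NULL, c("train", "val")))
  stall <- 0L
  for (ep in seq_len(epochs)) {
    p <- .unflatten_params(fl)
    fwd <- .encdec_forward(p, Xtr, hidden_size, keep_cache = TRUE)
    gr <- .encdec_backward(p, Xtr, fwd, hidden_size)
    gfl <- list(enc.Wx = gr$enc$Wx, enc.Wh = gr$enc$Wh, enc.b = gr$enc$b,
                dec.Wx = gr$dec$Wx, dec.Wh = gr$dec$Wh, dec.b = gr$dec$b,
                Wy = gr$Wy, by = gr$by)
    up <- .adam_update(fl, gfl, st, lr)
    fl <- up$p; st <- up$st
    vloss <- .encdec_forward(.unflatten_params(fl), Xva, hidden_size)$loss
    history[ep, ] <- c(fwd$loss, vloss)
    if (vloss < best$loss - 1e-7) {
      best <- list(loss = vloss, fl = fl)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  p <- .unflatten_params(best$fl)

  # error model from the held-out segments, per-day averaged
  Eva <- .per_day_errors(p, Xva, segs$starts[va_idx], nrow(x), hidden_size)
  em <- fit_error_model(Eva[rowSums(is.finite(Eva)) > 0, , drop = FALSE],
                        ridge_cond = ridge_cond)

  structure(list(params = p, hidden_size = hidden_size, window = window,
                 center = segs$center, scale = segs$scale,
                 feature_names = colnames(x),
                 error_model = em, history = history[!is.na(history[, 1]), ,
                                                     drop = FALSE],
                 n_train_days = nrow(x), n_segments = nb,
                 seed = seed, lr = lr, epochs = epochs,
                 val_frac = val_frac, ridge_cond = ridge_cond),
            class = "encdec_ad")
}

# reconstruct a batch and spread |x - xhat| back onto days; days covered by
# several overlapping segments get the average of their error vectors
.per_day_errors <- function(p, X, starts, n_days, hidden) {
  Tlen <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  E <- matrix(0, n_days, D)
  cnt <- numeric(n_days)
  if (B == 0) { E[] <- NA_real_; return(E) }
  fwd <- .encdec_forward(p, X, hidden)
  for (b in seq_len(B)) {
    err <- abs(matrix(fwd$Y[Tlen:1, b, ], Tlen, D) - matrix(X[, b, ], Tlen, D))
    rows <- starts[b]:(starts[b] + Tlen - 1L)
    E[rows, ] <- E[rows, ] + err
    cnt[rows] <- cnt[rows] + 1
  }
  E <- E / ifelse(cnt > 0, cnt, NA_real_)
  E
}

#' Per-day reconstruction error vectors
#'
#' Applies a fitted [encdec_ad()] model to a (possibly unseen) daily feature
#' series: the series is normalized with the *training* statistics, cut into
#' sliding segments, reconstructed, and the componentwise absolute errors
#' `e(i) = |x(i) - x_hat(i)|` are averaged over all segments covering each
#' day.
#'
#' @param model A fitted `encdec_ad` object.
#' @param x Feature matrix or [feature_table()] data frame.
#' @return Matrix (days x features) of error vectors; rows not covered by
#'   any full segment are `NA`.
#' @export
error_vectors <- function(model, x) {
  stopifnot(inherits(model, "encdec_ad"))
  x <- .as_feature_matrix(x)
  segs <- make_segments(x, window = model$window,
                        center = model$center, scale = model$scale)
  .per_day_errors(model$params, segs$arr, segs$starts, nrow(x),
                  model$hidden_size)
}

#' Maximum-likelihood normal model of reconstruction errors
#'
#' Fits `N(mu, Sigma)` to error vectors from relapse-free data by maximum
#' likelihood (covariance normalized by `1/N`). If the covariance is
#' ill-conditioned, the smallest power-of-ten ridge bringing its condition
#' number below `ridge_cond` is added to the diagonal.
#'
#' @param errors Matrix of error vectors (rows = days).
#' @param ridge_cond Condition-number ceiling.
#' @return An object of class `error_model`: `mu`, `Sigma` (unregularized
#'   MLE), `ridge`, `Sigma_reg`.
#' @export
fit_error_model <- function(errors, ridge_cond = 1e8) {
  errors <- as.matrix(errors)
  errors <- errors[stats::complete.cases(errors), , drop = FALSE]
  n <- nrow(errors)
  if (n < 2L) stop("need at least 2 error vectors to fit the error model")
  mu <- colMeans(errors)
  Xc <- sweep(errors, 2, mu, "-")
  Sigma <- crossprod(Xc) / n
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(ev); lam_min <- min(ev)
  ridge <- 0
  if (!is.finite(lam_min / lam_max) || lam_max <= 0 ||
      lam_max / max(lam_min, 0) > ridge_cond) {
    need <- max((lam_max - ridge_cond * lam_min) / (ridge_cond - 1), 1e-300)
    ridge <- 10^ceiling(log10(need))
  }
  structure(list(mu = mu, Sigma = Sigma, ridge = ridge,
                 Sigma_reg = Sigma + diag(ridge, length(mu))),
            class = "error_model")
}

#' Mahalanobis anomaly score
#'
#' `a(i) = sqrt((e(i) - mu)^T Sigma^{-1} (e(i) - mu))` under the fitted
#' normal error model. Computed via a Cholesky solve, never an explicit
#' inverse.
#'
#' @param e Error vector, or a matrix of error vectors (one per row).
#' @param model An [fit_error_model()] result.
#' @return Non-negative score(s); `NA` for rows with missing entries.
#' @export
anomaly_score <- function(e, model) {
  stopifnot(inherits(model, "error_model"))
  E <- if (is.matrix(e)) e else matrix(e, nrow = 1)
  out <- rep(NA_real_, nrow(E))
  ok <- stats::complete.cases(E)
  if (any(ok)) {
    Xc <- sweep(E[ok, , drop = FALSE], 2, model$mu, "-")
    R <- chol(model$Sigma_reg)
    w <- backsolve(R, t(Xc), transpose = TRUE)  # R^T w = Xc^T
    out[ok] <- sqrt(colSums(w^2))
  }
  if (is.matrix(e)) out else out[1]
}

# ---- methods -----------------------------------------------------------------

#' @export
print.encdec_ad <- function(x, ...) {
  cat("<encdec_ad> N-of-1 LSTM encoder-decoder\n")
  cat("  features:", length(x$center), " hidden:", x$hidden_size,
      " window:", x$window, "days\n")
  cat("  trained on", x$n_train_days, "days (", x$n_segments, "segments ),",
      nrow(x$history), "epochs\n")
  cat("  final validation MSE:", signif(min(x$history[, "val"]), 4), "\n")
  invisible(x)
}

#' @export
summary.encdec_ad <- function(object, ...) {
  em <- object$error_model
  cat("Per-patient LSTM encoder-decoder anomaly detector\n\n")
  print(object)
  cat("\nError model (held-out reconstruction errors):\n")
  cat("  mu:", paste(signif(em$mu, 3), collapse = " "), "\n")
  cat("  ridge:", em$ridge, "\n")
  invisible(object)
}

#' @export
predict.encdec_ad <- function(object, newdata,
                              type = c("score", "errors", "reconstruction"),
                              ...) {
  type <- match.arg(type)
  x <- .as_feature_matrix(newdata)
  if (type == "reconstruction") {
    segs <- make_segments(x, window = object$window,
                          center = object$center, scale = object$scale)
    fwd <- .encdec_forward(object$params, segs$arr, object$hidden_size)
    Tlen <- object$window
    return(fwd$Y[Tlen:1, , , drop = FALSE])   # back in forward time order
  }
  E <- error_vectors(object, x)
  if (type == "errors") return(E)
  anomaly_score(E, object$error_model)
}

#' @export
residuals.encdec_ad <- function(object, x, ...) {
  if (missing(x)) stop("supply the feature series to compute residuals on")
  error_vectors(object, x)
}
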