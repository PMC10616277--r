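test_that("segment construction counts, normalizes and imputes correctly", {
  set.seed(1)
  x <- matrix(rnorm(20 * 8), 20, 8)
  s <- make_segments(x)
  expect_equal(length(s$starts), 7L)                 # 20 - 14 + 1
  expect_equal(dim(s$arr), c(14L, 7L, 8L))
  # a fully missing feature column becomes all zeros after imputation
  x2 <- x; x2[, 3] <- NA
  s2 <- make_segments(x2)
  expect_true(all(s2$arr[, , 3] == 0))
  # test segments must use the training statistics, not their own
  xt <- x + 5
  st <- make_segments(xt, center = s$center, scale = s$scale)
  expect_equal(st$arr[1, 1, ], (xt[1, ] - s$center) / s$scale)
  expect_message(make_segments(x[1:5, ]), "fewer than")
})

test_that("analytic BPTT gradients match numerical differentiation", {
  ns <- asNamespace("nof1relapse")
  set.seed(99)
  Tn <- 3; B <- 2; D <- 2; H <- 3
  X <- array(rnorm(Tn * B * D), dim = c(Tn, B, D))
  p <- ns$.lstm_init(D, H)
  fwd <- ns$.encdec_forward(p, X, H, keep_cache = TRUE)
  gr <- ns$.encdec_backward(p, X, fwd, H)
  gfl <- list(enc.Wx = gr$enc$Wx, enc.Wh = gr$enc$Wh, enc.b = gr$enc$b,
              dec.Wx = gr$dec$Wx, dec.Wh = gr$dec$Wh, dec.b = gr$dec$b,
              Wy = gr$Wy, by = gr$by)
  fl <- ns$.flatten_params(p)
  eps <- 1e-6
  for (nm in names(fl)) {
    g_num <- fl[[nm]] * 0
    for (k in seq_along(fl[[nm]])) {
      f2 <- fl; f2[[nm]][k] <- f2[[nm]][k] + eps
      lp <- ns$.encdec_forward(ns$.unflatten_params(f2), X, H)$loss
      f2[[nm]][k] <- f2[[nm]][k] - 2 * eps
      lm_ <- ns$.encdec_forward(ns$.unflatten_params(f2), X, H)$loss
      g_num[k] <- (lp - lm_) / (2 * eps)
    }
    expect_lt(max(abs(g_num - gfl[[nm]])) / max(1e-6, max(abs(g_num))), 1e-4)
  }
})

test_that("training is deterministic under seed and learns constant input", {
  x <- matrix(rep(c(3, -1, 0.5, 2, 1, -2, 0, 4), each = 30), 30, 8)
  x <- x + 0                                  # constant features
  m1 <- encdec_ad(x, hidden_size = 8, epochs = 40, seed = 5)
  m2 <- encdec_ad(x, hidden_size = 8, epochs = 40, seed = 5)
  expect_identical(m1$params, m2$params)      # bit-reproducible
  expect_lt(min(m1$history[, "train"]), 1e-3) # constant is learnable
})

test_that("reconstruction is better on structured than on permuted data", {
  x <- make_sine_features(60, seed = 2)
  m <- encdec_ad(x, hidden_size = 16, epochs = 120, seed = 3)
  held <- make_sine_features(30, seed = 7)
  set.seed(8)
  perm <- held[sample(nrow(held)), ]
  e_held <- mean(error_vectors(m, held), na.rm = TRUE)
  e_perm <- mean(error_vectors(m, perm), na.rm = TRUE)
  expect_lt(e_held, e_perm)
})

test_that("error vectors are componentwise absolute residuals", {
  x <- make_sine_features(40, seed = 4)
  m <- encdec_ad(x, hidden_size = 8, epochs = 30, seed = 1)
  # single segment: per-day errors equal |z - zhat| directly
  one <- x[1:14, ]
  z <- sweep(sweep(one, 2, m$center, "-"), 2, m$scale, "/")
  rec <- predict(m, one, type = "reconstruction")
  manual <- abs(z - matrix(rec[, 1, ], 14, 8))
  expect_equal(error_vectors(m, one), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  # invariant to joint sign flip of target and reconstruction
  expect_true(all(manual >= 0))
})

test_that("error model is the 1/N MLE and is permutation invariant", {
  em <- fit_error_model(matrix(c(1, 3), ncol = 1))
  expect_equal(em$mu, 2, ignore_attr = TRUE)
  expect_equal(as.numeric(em$Sigma), 1)       # MLE, not 1/(N-1)
  set.seed(12)
  E <- matrix(rnorm(40), 10, 4)
  em1 <- fit_error_model(E)
  em2 <- fit_error_model(E[sample(10), ])
  expect_equal(em1$mu, em2$mu)
  expect_equal(em1$Sigma, em2$Sigma)
  expect_error(fit_error_model(E[1, , drop = FALSE]), "at least 2")
})

test_that("singular covariance engages the ridge and keeps scores finite", {
  E <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)  # identical vectors
  em <- fit_error_model(E)
  expect_gt(em$ridge, 0)
  ev <- eigen(em$Sigma_reg, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))                      # positive definite post-ridge
  expect_true(is.finite(anomaly_score(c(2, 2, 2), em)))
})

test_that("Mahalanobis score matches closed forms and a solve oracle", {
  em <- structure(list(mu = rep(0, 6), Sigma = diag(6), ridge = 0,
                       Sigma_reg = diag(6)), class = "error_model")
  expect_equal(anomaly_score(rep(0, 6), em), 0)
  expect_equal(anomaly_score(c(3, 4, 0, 0, 0, 0), em), 5)
  em2 <- structure(list(mu = c(0, 0),
                        Sigma = matrix(c(2, 1, 1, 2), 2),
                        ridge = 0,
                        Sigma_reg = matrix(c(2, 1, 1, 2), 2)),
                   class = "error_model")
  expect_equal(anomaly_score(c(1, 1), em2), sqrt(2 / 3))
  # random SPD fixtures against an independent solve()
  set.seed(77)
  for (i in 1:10) {
    d <- sample(2:8, 1)
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) + diag(0.1, d)
    mu <- rnorm(d); e <- rnorm(d)
    em3 <- structure(list(mu = mu, Sigma = S, ridge = 0, Sigma_reg = S),
                     class = "error_model")
    oracle <- sqrt(drop(t(e - mu) %*% solve(S, e - mu)))
    expect_equal(anomaly_score(e, em3), oracle, tolerance = 1e-8)
  }
})

test_that("a sustained multivariate mean shift separates the scores", {
  # 10 seeded replicates: median score in a 14-day window shifted by
  # 3 training SDs in 4 of 8 features exceeds the 95th percentile of
  # clean-period scores
  hits <- 0L
  for (s in 1:10) {
    x <- make_sine_features(70, seed = s, noise = 0.2)
    m <- encdec_ad(x, hidden_size = 12, epochs = 60, seed = s)
    clean <- make_sine_features(40, seed = 100 + s, noise = 0.2)
    shifted <- clean
    shifted[20:33, 1:4] <- shifted[20:33, 1:4] +
      3 * rep(m$scale[1:4], each = 14)
    sc_clean <- predict(m, clean)
    sc_shift <- predict(m, shifted)
    q95 <- quantile(sc_clean, 0.95, na.rm = TRUE)
    if (isTRUE(median(sc_shift[20:33], na.rm = TRUE) > q95)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
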