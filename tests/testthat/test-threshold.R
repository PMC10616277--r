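# independent straight-line evaluation of the dynamic-threshold rule,
# used as the oracle for the fixtures below
threshold_oracle <- function(x, span = 7, zg = seq(2, 10, 0.5), p = 0.13) {
  a <- 2 / (span + 1); s <- numeric(length(x)); s[1] <- x[1]
  for (t in 2:length(x)) s[t] <- a * x[t] + (1 - a) * s[t - 1]
  mu <- mean(s); sdv <- sd(s)
  if (sdv == 0) return(integer(0))
  best <- -Inf; beps <- NA
  for (z in zg) {
    eps <- mu + z * sdv; ab <- s > eps
    if (!any(ab) || all(ab)) next
    r <- rle(ab); nseq <- sum(r$values)
    obj <- ((mu - mean(s[!ab])) / mu + (sdv - sd(s[!ab])) / sdv) /
      (sum(ab) + nseq^2)
    if (obj >= best) { best <- obj; beps <- eps }
  }
  if (!is.finite(best)) return(integer(0))
  ab <- s > beps
  r <- rle(ab); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ks <- which(r$values)
  mx <- sapply(ks, function(k) max(s[starts[k]:ends[k]]))
  ord <- order(mx, decreasing = TRUE)
  nom <- if (any(!ab)) max(s[!ab]) else min(mx)
  m <- c(mx[ord], nom)
  prune <- integer(0)
  for (i in seq_along(ord)) {
    d <- (m[i] - m[i + 1]) / m[i]
    if (is.finite(d) && d < p) prune <- c(prune, ord[i])
    else prune <- integer(0)
  }
  keep <- setdiff(seq_along(ks), prune)
  sort(unlist(lapply(keep, function(k) starts[ks[k]]:ends[ks[k]])))
}

test_that("a lone large spike on flat background is flagged", {
  x <- rep(1, 100); x[50] <- 20
  got <- detect_anomalous_instances(x)
  expect_equal(as.integer(got), threshold_oracle(x))
  expect_true(50 %in% got)
  expect_true(all(got %in% c(50L, 51L)))    # spike plus its smoothing shadow
})

test_that("constant scores yield no instances", {
  expect_length(detect_anomalous_instances(rep(3, 50)), 0)
  expect_length(detect_anomalous_instances(rep(0, 14)), 0)
  expect_length(detect_anomalous_instances(5), 0)
})

test_that("two equal spikes both survive pruning", {
  x <- rep(1, 100); x[30] <- 20; x[70] <- 20
  got <- detect_anomalous_instances(x)
  expect_equal(as.integer(got), threshold_oracle(x))
  expect_true(all(c(30, 70) %in% got))
})

test_that("i.i.d. Gaussian scores mostly produce no instances", {
  clean <- vapply(1:20, function(s) {
    set.seed(s)
    length(detect_anomalous_instances(abs(rnorm(60)))) == 0
  }, logical(1))
  expect_gte(sum(clean), 10L)
})

test_that("blockwise detection catches the leading edge of a sustained shift", {
  set.seed(4)
  x <- c(abs(rnorm(40, 1, 0.2)), abs(rnorm(40, 12, 0.5)))
  glob <- detect_anomalous_instances(x)              # absorbed into stats
  blk <- detect_anomalous_instances(x, block = 14)
  expect_true(any(blk %in% 41:48))                   # onset found locally
  expect_true(length(blk) >= length(glob))
  # agreement with the global pass when the series fits in one block
  short <- rep(1, 12); short[6] <- 9
  expect_equal(detect_anomalous_instances(short, block = 14),
               detect_anomalous_instances(short),
               ignore_attr = TRUE)
})

test_that("daily labels carry instances forward seven days", {
  days <- 1:30
  lab <- daily_anomaly_labels(10L, days)
  expect_equal(which(lab), 10:16)
  expect_false(any(daily_anomaly_labels(integer(0), days)))
  lab2 <- daily_anomaly_labels(c(10L, 12L), days)
  expect_equal(which(lab2), sort(union(10:16, 12:18)))
})

test_that("weekly downsampling flags any week containing a labeled day", {
  anchor <- as.Date("2022-01-03")
  days <- anchor + 0:27                               # four full weeks
  lab <- rep(FALSE, 28); lab[9] <- TRUE               # one day in week 1
  wf <- weekly_flags(days, lab, anchor)
  expect_equal(wf$flag, c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(weekly_flags(days, rep(FALSE, 28), anchor)$flag))
  # an instance on the last day of a week spills into the next week
  inst <- days[14]                                    # last day of week 1
  lab3 <- daily_anomaly_labels(inst, days)
  wf3 <- weekly_flags(days, lab3, anchor)
  expect_true(all(wf3$flag[wf3$week %in% c(1, 2)]))
})
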