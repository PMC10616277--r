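.ewma <- function(x, span) {
  a <- 2 / (span + 1)
  s <- numeric(length(x))
  s[1] <- x[1]
  for (t in seq_along(x)[-1]) s[t] <- a * x[t] + (1 - a) * s[t - 1]
  s
}

.runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Adaptive detection of anomalous instances in an anomaly-score sequence
#'
#' Nonparametric dynamic thresholding in the style of Hundman et al.'s
#' telemetry anomaly detector: the score sequence is smoothed with an EWMA;
#' candidate thresholds `mean + z * sd` of the smoothed scores are evaluated
#' over a grid of `z`, each scored by the relative drop in mean and spread
#' once supra-threshold points are removed, penalized by the number of
#' flagged points plus the squared number of flagged sequences; the best
#' threshold's sequences are then pruned unless each sequence maximum
#' exceeds the next retained maximum by the minimum percent decrease `p`.
#'
#' @param scores Non-negative anomaly scores, one per day, in time order.
#' @param ewma_span EWMA span for smoothing.
#' @param z_grid Candidate threshold multipliers.
#' @param prune_p Minimum percent decrease between successive sequence
#'   maxima for a sequence to survive pruning.
#' @param block When non-`NULL`, instances are determined within each
#'   `block`-day window advancing one day at a time and the union of
#'   flagged positions is returned. A local threshold keeps a sustained
#'   upward shift detectable at its leading edge, where a single global
#'   threshold would absorb it into the background statistics.
#' @return Integer vector of flagged positions (possibly empty), with the
#'   chosen threshold in attribute `"threshold"` and the smoothed scores in
#'   `"smoothed"`. A constant sequence yields no instances.
#' @export
detect_anomalous_instances <- function(scores, ewma_span = 7,
                                       z_grid = seq(2, 10, by = 0.5),
                                       prune_p = 0.13, block = NULL) {
  stopifnot(length(scores) >= 1)
  scores[!is.finite(scores)] <- 0
  if (!is.null(block) && length(scores) > block) {
    idx <- integer(0)
    for (s0 in seq_len(length(scores) - block + 1L)) {
      loc <- detect_anomalous_instances(scores[s0:(s0 + block - 1L)],
                                        ewma_span = ewma_span,
                                        z_grid = z_grid, prune_p = prune_p)
      idx <- union(idx, s0 - 1L + loc)
    }
    return(structure(sort(as.integer(idx)), threshold = NA_real_,
                     smoothed = .ewma(scores, ewma_span)))
  }
  s <- .ewma(scores, ewma_span)
  mu <- mean(s); sdev <- sd(s)
  empty <- structure(integer(0), threshold = NA_real_, smoothed = s)
  if (length(s) < 2L || is.na(sdev) || sdev == 0) return(empty)

  best <- list(obj = -Inf, eps = NA_real_)
  for (z in z_grid) {
    eps <- mu + z * sdev
    above <- s > eps
    n_pts <- sum(above)
    if (n_pts == 0 || n_pts == length(s)) next
    runs <- .runs_above(above)
    mu_r <- mean(s[!above]); sd_r <- sd(s[!above])
    if (is.na(sd_r)) sd_r <- 0
    obj <- ((mu - mu_r) / mu + (sdev - sd_r) / sdev) /
      (n_pts + nrow(runs)^2)
    if (obj >= best$obj) best <- list(obj = obj, eps = eps)  # ties -> larger z
  }
  if (!is.finite(best$obj)) return(empty)

  eps <- best$eps
  above <- s > eps
  runs <- .runs_above(above)
  maxima <- vapply(seq_len(nrow(runs)),
                   function(k) max(s[runs$start[k]:runs$end[k]]), numeric(1))
  ord <- order(maxima, decreasing = TRUE)
  nominal_max <- if (any(!above)) max(s[!above]) else min(maxima)
  m <- c(maxima[ord], nominal_max)
  # walk the sorted maxima; runs of small decreases at the tail are pruned,
  # but a later decrease exceeding p rescues everything above it
  to_prune <- integer(0)
  for (i in seq_along(ord)) {
    d <- (m[i] - m[i + 1]) / m[i]
    if (is.finite(d) && d < prune_p) to_prune <- c(to_prune, ord[i])
    else to_prune <- integer(0)
  }
  keep <- setdiff(seq_len(nrow(runs)), to_prune)
  idx <- sort(unique(unlist(lapply(keep, function(k)
    runs$start[k]:runs$end[k]))))
  structure(as.integer(idx), threshold = eps, smoothed = s)
}

#' Trailing 7-day anomaly labels
#'
#' A day is labeled anomalous when an anomalous instance occurred within
#' the trailing week (`[d - horizon + 1, d]`), aligning the passive signal
#' with self-report questionnaires whose recall period covers the previous
#' 7 days.
#'
#' @param instance_days Days (integer indices or `Date`) of detected
#'   anomalous instances.
#' @param days All days to label (same type as `instance_days`).
#' @param horizon Trailing window length in days.
#' @return Logical vector along `days`.
#' @export
daily_anomaly_labels <- function(instance_days, days, horizon = 7) {
  if (!length(instance_days)) return(rep(FALSE, length(days)))
  vapply(days, function(d) any(instance_days > d - horizon & instance_days <= d),
         logical(1))
}

#' Down-sample daily anomaly labels to weekly flags
#'
#' Weeks are 7-day blocks anchored at the patient's enrollment date (the
#' survey schedule). A week is flagged when any of its days is labeled
#' anomalous.
#'
#' @param days Day identifiers (`Date` or integer day offsets).
#' @param labels Logical daily anomaly labels along `days`.
#' @param anchor Enrollment date (or day offset 0) anchoring week 0.
#' @return Data frame with `week` (integer index from enrollment) and
#'   `flag`.
#' @export
weekly_flags <- function(days, labels, anchor) {
  wk <- as.integer(floor(as.numeric(days - anchor) / 7))
  agg <- tapply(labels, wk, any)
  data.frame(week = as.integer(names(agg)), flag = as.logical(agg),
             row.names = NULL)
}
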