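#' Quality-control parameters for activity count streams
#'
#' Thresholds used when screening minute-resolution activity counts for
#' artifacts and when selecting segments suitable for fractal analysis.
#'
#' @param spike_sd_threshold Flag a minute whose count deviates from the
#'   record-wide mean by at least this many standard deviations (two-sided).
#' @param zero_run_threshold Flag runs of zero (or missing) minutes whose
#'   duration strictly exceeds this many minutes.
#' @param dfa_max_gap Largest gap (minutes) tolerated inside a segment used
#'   for detrended fluctuation analysis; the default is 5% of a day.
#' @param window_days Trailing window (days) searched for a valid segment.
#' @param min_continuous_days Minimum number of consecutive clean days a
#'   fractal-analysis segment must span.
#'
#' @return An object of class `quality_params`.
#' @export
quality_params <- function(spike_sd_threshold = 10,
                           zero_run_threshold = 60,
                           dfa_max_gap = 72,
                           window_days = 7,
                           min_continuous_days = 2) {
  stopifnot(spike_sd_threshold > 0, zero_run_threshold > 0,
            dfa_max_gap > 0, window_days > 0, min_continuous_days > 0)
  structure(list(spike_sd_threshold = spike_sd_threshold,
                 zero_run_threshold = zero_run_threshold,
                 dfa_max_gap = dfa_max_gap,
                 window_days = window_days,
                 min_continuous_days = min_continuous_days),
            class = "quality_params")
}

#' Minute-resolution activity series
#'
#' Container for one patient's activity counts at one-minute resolution.
#' Days are stored as a contiguous calendar span; each day holds exactly
#' 1440 slots and minutes without data are `NA`.
#'
#' @param patient_id Patient identifier.
#' @param days Vector of class `Date`, one entry per row of `counts`,
#'   strictly increasing by one day.
#' @param counts Numeric matrix with one row per day and 1440 columns
#'   (minute of day, starting at local midnight). `NA` marks missing minutes;
#'   non-missing counts must be non-negative.
#'
#' @return An object of class `minute_series`.
#' @export
minute_series <- function(patient_id, days, counts) {
  days <- as.Date(days)
  counts <- as.matrix(counts)
  if (ncol(counts) != 1440L)
    stop("`counts` must have 1440 columns (minutes of the day)")
  if (nrow(counts) != length(days))
    stop("one row of `counts` per day is required")
  if (length(days) > 1L && any(diff(as.integer(days)) != 1L))
    stop("`days` must be consecutive calendar dates")
  if (any(counts < 0, na.rm = TRUE))
    stop("activity counts must be non-negative")
  structure(list(patient_id = patient_id, days = days, counts = counts),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  n_miss <- sum(is.na(x$counts))
  cat("<minute_series> patient", x$patient_id, "\n")
  cat("  ", length(x$days), "days (", format(x$days[1]), "to",
      format(x$days[length(x$days)]), ")\n")
  cat("  ", n_miss, "missing minutes (",
      sprintf("%.1f%%", 100 * n_miss / length(x$counts)), ")\n")
  invisible(x)
}

#' @export
as.data.frame.minute_series <- function(x, ...) {
  data.frame(patient_id = x$patient_id,
             date = rep(x$days, each = 1440L),
             minute_of_day = rep(0:1439, length(x$days)),
             counts = as.vector(t(x$counts)))
}

#' Resample epoch-level activity counts to minute resolution
#'
#' Device activity counts arrive in 15-second or 60-second epochs. Counts are
#' summed within each clock minute, giving 1440 values per day; minutes with
#' no covering epoch are missing. Total counts are conserved over covered
#' minutes.
#'
#' @param epochs A data frame with columns `patient_id`, `timestamp`
#'   (`POSIXct`, or a string parseable as ISO-8601) and `counts`
#'   (non-negative). A single patient per call. Dropped epochs are allowed:
#'   timestamps must be strictly increasing and all spacings must be integer
#'   multiples of the base epoch length (15 s or 60 s), which is auto-detected
#'   as the smallest spacing.
#' @param tz Time zone used when parsing character timestamps.
#'
#' @return A [minute_series()].
#' @export
resample_to_minute <- function(epochs, tz = "UTC") {
  req <- c("patient_id", "timestamp", "counts")
  if (!all(req %in% names(epochs)))
    stop("`epochs` needs columns patient_id, timestamp, counts")
  if (length(unique(epochs$patient_id)) != 1L)
    stop("`resample_to_minute` handles one patient at a time")
  ts <- epochs$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(sub("T", " ", as.character(ts), fixed = TRUE), tz = tz)
  if (anyNA(ts)) stop("unparseable timestamps in `epochs`")
  cnt <- epochs$counts
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be present and non-negative")
  o <- order(ts)
  ts <- ts[o]; cnt <- cnt[o]
  if (length(ts) > 1L) {
    d <- as.numeric(diff(ts), units = "secs")
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    base <- min(d)
    if (!base %in% c(15, 60))
      stop("epoch spacing must be 15 s or 60 s (observed ", base, " s)")
    if (any(abs(d / base - round(d / base)) > 1e-6))
      stop("irregular epoch spacing: gaps must be whole multiples of ", base, " s")
  }
  day <- as.Date(ts, tz = tz)
  sec_of_day <- as.numeric(ts) - as.numeric(as.POSIXct(paste(day, "00:00:00"), tz = tz))
  minute <- floor(sec_of_day / 60)

  days <- seq(min(day), max(day), by = "day")
  counts <- matrix(NA_real_, nrow = length(days), ncol = 1440L)
  di <- match(day, days)
  idx <- (di - 1L) * 1440L + minute + 1L   # row-major slot index
  agg <- rowsum(cnt, idx)
  slot <- as.integer(rownames(agg))
  flat <- as.vector(t(counts))
  flat[slot] <- agg[, 1L]
  counts <- matrix(flat, nrow = length(days), byrow = TRUE)
  minute_series(epochs$patient_id[1L], days, counts)
}

#' Flag gaps, zero runs and amplitude spikes in a minute series
#'
#' Implements the signal-quality screen applied before feature extraction:
#' missing minutes, runs of zero/missing minutes longer than
#' `zero_run_threshold` (strictly), and isolated spikes deviating at least
#' `spike_sd_threshold` standard deviations from the record-wide mean are all
#' labeled as gaps. Missing minutes count toward zero runs because device-off
#' time is indistinguishable from inactivity for windowing purposes.
#'
#' @param series A [minute_series()].
#' @param params A [quality_params()].
#'
#' @return An object of class `gap_mask`: a list with `mask` (logical matrix,
#'   `TRUE` = gap, same shape as `series$counts`) and `runs` (data frame of
#'   gap runs over the flattened timeline: `start`, `length`, both in
#'   minutes, 1-based from the first minute of the first day).
#' @export
detect_gaps <- function(series, params = quality_params()) {
  stopifnot(inherits(series, "minute_series"), inherits(params, "quality_params"))
  v <- as.vector(t(series$counts))        # flattened timeline
  miss <- is.na(v)
  if (all(miss)) stop("all minutes missing: cannot screen an empty record")

  mask <- miss
  # zero-run rule: runs of zero-or-missing minutes strictly longer than the
  # threshold
  zr <- rle(miss | (!miss & v == 0))
  ends <- cumsum(zr$lengths)
  starts <- ends - zr$lengths + 1L
  long0 <- which(zr$values & zr$lengths > params$zero_run_threshold)
  for (k in long0) mask[starts[k]:ends[k]] <- TRUE

  # spike rule: two-sided deviation from the patient-global mean
  mu <- mean(v[!miss]); s <- sd(v[!miss])
  if (is.na(s) || s == 0) {
    message("zero-variance record: spike rule skipped, zero-run rule only")
  } else {
    mask[!miss & abs(v - mu) >= params$spike_sd_threshold * s] <- TRUE
  }

  rr <- rle(mask)
  rends <- cumsum(rr$lengths)
  rstarts <- rends - rr$lengths + 1L
  keep <- which(rr$values)
  runs <- data.frame(start = rstarts[keep], length = rr$lengths[keep])
  structure(list(mask = matrix(mask, nrow = nrow(series$counts), byrow = TRUE),
                 runs = runs),
            class = "gap_mask")
}

#' @export
print.gap_mask <- function(x, ...) {
  cat("<gap_mask>", sum(x$mask), "flagged minutes in", nrow(x$runs), "runs\n")
  invisible(x)
}

# Day-level validity: a day is usable for fractal analysis unless a gap run
# longer than `dfa_max_gap` touches it (runs computed on the timeline of the
# trailing window, with absent days treated as all-gap).
.valid_day_flags <- function(gapvec, n_days, max_gap) {
  ok <- rep(TRUE, n_days)
  r <- rle(gapvec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths > max_gap)) {
    d1 <- (starts[k] - 1L) %/% 1440L + 1L
    d2 <- (ends[k] - 1L) %/% 1440L + 1L
    ok[d1:d2] <- FALSE
  }
  ok
}

#' Most recent continuous segment suitable for fractal analysis
#'
#' Searches the trailing `window_days` ending at `day` for the most recent
#' run of at least `min_continuous_days` consecutive days in which no single
#' gap exceeds `dfa_max_gap` minutes. Gaps within the tolerance are retained
#' as missing minutes (they are skipped, not imputed, during detrending).
#'
#' @param series A [minute_series()].
#' @param mask A [detect_gaps()] result aligned with `series`.
#' @param day Target day (`Date`); must lie within the series.
#' @param params A [quality_params()].
#'
#' @return `NULL` when no qualifying run exists, otherwise a list with
#'   `days` (the segment's dates) and `counts` (concatenated minute counts
#'   with `NA` at flagged minutes).
#' @export
valid_dfa_segment <- function(series, mask, day, params = quality_params()) {
  day <- as.Date(day)
  if (!day %in% series$days) stop("`day` is not covered by the series")
  window <- seq(day - params$window_days + 1, day, by = "day")
  present <- window %in% series$days
  gap <- rep(TRUE, length(window) * 1440L)
  for (i in which(present)) {
    ri <- match(window[i], series$days)
    gap[((i - 1L) * 1440L + 1L):(i * 1440L)] <- mask$mask[ri, ]
  }
  ok <- .valid_day_flags(gap, length(window), params$dfa_max_gap) & present

  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= params$min_continuous_days)
  if (!length(cand)) return(NULL)
  k <- cand[length(cand)]                 # most recent qualifying run
  seg_days <- window[starts[k]:ends[k]]
  ri <- match(seg_days, series$days)
  cnts <- as.vector(t(series$counts[ri, , drop = FALSE]))
  m <- as.vector(t(mask$mask[ri, , drop = FALSE]))
  cnts[m] <- NA_real_
  list(days = seg_days, counts = cnts)
}

#' Write / read a minute series as CSV
#'
#' The on-disk schema is `patient_id, date, minute_of_day, counts, is_gap`
#' with empty `counts` for missing minutes.
#'
#' @param series A [minute_series()].
#' @param mask Optional [detect_gaps()] result supplying the `is_gap` column.
#' @param path Output file.
#' @return `write_minutes_csv` returns `path` invisibly; `read_minutes_csv`
#'   returns a list with elements `series` and `gap` (logical matrix or
#'   `NULL`).
#' @export
write_minutes_csv <- function(series, path, mask = NULL) {
  df <- as.data.frame(series)
  df$is_gap <- if (is.null(mask)) is.na(df$counts) else as.vector(t(mask$mask))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_minutes_csv
#' @export
read_minutes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  days <- sort(unique(as.Date(df$date)))
  counts <- matrix(NA_real_, length(days), 1440L)
  idx <- cbind(match(as.Date(df$date), days), df$minute_of_day + 1L)
  counts[idx] <- df$counts
  gap <- NULL
  if ("is_gap" %in% names(df)) {
    gap <- matrix(FALSE, length(days), 1440L)
    gap[idx] <- as.logical(df$is_gap)
  }
  list(series = minute_series(df$patient_id[1L], days, counts), gap = gap)
}
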