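# 6-hour epoch boundaries (minute-of-day, 1-based column index ranges)
.epoch_spans <- function() {
  list(day       = 1:1440,
       morning   = 361:720,    #  6 a.m. - 12 p.m.
       afternoon = 721:1080,   # 12 p.m. -  6 p.m.
       evening   = 1081:1440,  #  6 p.m. - 12 a.m.
       night     = 1:360)      # 12 a.m. -  6 a.m.
}

.feature_names <- c("alpha1", "alpha2", "mfdfa_width", "saen_day",
                    "saen_morning", "saen_afternoon", "saen_evening",
                    "saen_night")

# single-day sample entropy per span; NA when the span has an identified gap
# or a degenerate (zero-variance-increment / no-match) signal
.saen_day_values <- function(series, mask, row, saen) {
  spans <- .epoch_spans()
  vapply(spans, function(cols) {
    if (any(mask$mask[row, cols])) return(NA_real_)
    v <- series$counts[row, cols]
    tryCatch(sample_entropy(v, saen), error = function(e) NA_real_)
  }, numeric(1))
}

#' Daily fractal and entropy feature vector
#'
#' Computes the eight-dimensional daily feature vector used by the anomaly
#' detector: DFA exponents `alpha1`/`alpha2` and the multifractal width on
#' the most recent valid segment (trailing 7-day window, at least 2 gap-free
#' consecutive days), plus sample entropy of the whole day and of each
#' 6-hour epoch, each taken as the median over the trailing 7 days that
#' contain no identified gap in that span (index day included). Features
#' without qualifying data are `NA`.
#'
#' @param series A [minute_series()].
#' @param mask The matching [detect_gaps()] result.
#' @param date Index day.
#' @param params [quality_params()] controlling segment selection.
#' @param saen [saen_params()].
#' @param scales Fluctuation-analysis scales.
#' @return A one-row data frame: `date` plus the eight features.
#' @export
daily_features <- function(series, mask, date, params = quality_params(),
                           saen = saen_params(), scales = dfa_scales()) {
  feature_table(series, mask, params = params, saen = saen, scales = scales,
                dates = as.Date(date))
}

#' Daily feature table for a whole record
#'
#' Batch version of [daily_features()]: one row per requested day. Per-day
#' sample entropies are computed once and shared across the overlapping
#' 7-day medians.
#'
#' @inheritParams daily_features
#' @param dates Days to evaluate (default: all days in the series).
#' @return A data frame with columns `date`, `alpha1`, `alpha2`,
#'   `mfdfa_width`, `saen_day`, `saen_morning`, `saen_afternoon`,
#'   `saen_evening`, `saen_night`.
#' @export
feature_table <- function(series, mask, params = quality_params(),
                          saen = saen_params(), scales = dfa_scales(),
                          dates = series$days) {
  dates <- as.Date(dates)
  if (!all(dates %in% series$days)) stop("some `dates` are outside the record")
  spans <- .epoch_spans()

  # cache single-day SaEn for every day that any trailing window touches
  need <- sort(unique(do.call(c, lapply(dates, function(d)
    seq(d - params$window_days + 1, d, by = "day")))))
  need <- need[need %in% series$days]
  sa_cache <- matrix(NA_real_, nrow = length(need), ncol = length(spans),
                     dimnames = list(format(need), names(spans)))
  for (i in seq_along(need)) {
    row <- match(need[i], series$days)
    sa_cache[i, ] <- .saen_day_values(series, mask, row, saen)
  }

  out <- matrix(NA_real_, nrow = length(dates), ncol = length(.feature_names),
                dimnames = list(NULL, .feature_names))
  for (i in seq_along(dates)) {
    d <- dates[i]
    seg <- valid_dfa_segment(series, mask, d, params)
    if (!is.null(seg)) {
      f2 <- .window_fluctuations(seg$counts, scales, 2)
      dres <- dfa(seg$counts, scales = scales, .f2 = f2)
      # only the width h(-5) - h(+5) enters the feature vector, so the
      # interior of the moment grid is skipped here
      mres <- suppressMessages(mfdfa(seg$counts, q_grid = c(-5, 5),
                                     scales = scales, .f2 = f2))
      out[i, "alpha1"] <- dres$alpha1
      out[i, "alpha2"] <- dres$alpha2
      out[i, "mfdfa_width"] <- mres$width
    }
    win <- seq(d - params$window_days + 1, d, by = "day")
    ci <- match(win, need)
    ci <- ci[!is.na(ci)]
    if (length(ci)) {
      med <- apply(sa_cache[ci, , drop = FALSE], 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) median(v) else NA_real_
      })
      out[i, c("saen_day", "saen_morning", "saen_afternoon",
               "saen_evening", "saen_night")] <-
        med[c("day", "morning", "afternoon", "evening", "night")]
    }
  }
  cbind(data.frame(date = dates), as.data.frame(out))
}

#' Write a per-patient daily feature table to CSV
#'
#' Schema: `patient_id, date, alpha1, alpha2, mfdfa_width, saen_day,
#' saen_morning, saen_afternoon, saen_evening, saen_night`, empty cells for
#' missing features.
#'
#' @param features A [feature_table()] result.
#' @param patient_id Patient identifier to prepend.
#' @param path Output file.
#' @export
write_features_csv <- function(features, patient_id, path) {
  write.csv(cbind(patient_id = patient_id, features), path,
            row.names = FALSE, na = "")
  invisible(path)
}
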