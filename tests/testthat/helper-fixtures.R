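# independent O(n^2) sample-entropy oracle: plain R loops, no shared code
# with the package's Rcpp kernel
saen_oracle <- function(x, m = 2, r = 0.2, delta = 1) {
  d <- diff(x)
  z <- (d - mean(d)) / sd(d)
  L <- length(z)
  N <- L - m * delta
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(z[i + k * delta] - z[j + k * delta]))
      if (dm < r) {
        B <- B + 1
        if (max(dm, abs(z[i + m * delta] - z[j + m * delta])) < r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# epoch-level data frame for one patient
make_epochs <- function(counts, spacing = 15, start = "2021-03-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(patient_id = "T1",
             timestamp = t0 + spacing * (seq_along(counts) - 1),
             counts = counts)
}

# minute series with given per-day count rows (list of length-1440 vectors)
make_minutes <- function(rows, start_day = as.Date("2021-03-01"), id = "T1") {
  minute_series(id, start_day + seq_along(rows) - 1, do.call(rbind, rows))
}

# binomial multiplicative cascade of length 2^levels (multifractal fixture)
make_cascade <- function(levels = 12, p = 0.7, seed = 1) {
  set.seed(seed)
  x <- rep(1, 2^levels)
  n <- length(x)
  for (l in seq_len(levels)) {
    seg <- n / 2^(l - 1)
    for (s in seq_len(2^(l - 1))) {
      i0 <- (s - 1) * seg
      w <- if (runif(1) < 0.5) c(p, 1 - p) else c(1 - p, p)
      x[(i0 + 1):(i0 + seg / 2)] <- x[(i0 + 1):(i0 + seg / 2)] * w[1]
      x[(i0 + seg / 2 + 1):(i0 + seg)] <- x[(i0 + seg / 2 + 1):(i0 + seg)] * w[2]
    }
  }
  x * n
}

# smooth multivariate feature series for encoder-decoder tests
make_sine_features <- function(n_days, d = 8, seed = 1, noise = 0.05) {
  set.seed(seed)
  t <- seq_len(n_days)
  phases <- runif(d, 0, 2 * pi)
  periods <- sample(5:11, d, replace = TRUE)
  x <- sapply(seq_len(d), function(j)
    sin(2 * pi * t / periods[j] + phases[j]) + rnorm(n_days, 0, noise))
  colnames(x) <- paste0("f", seq_len(d))
  x
}

# lightweight patient record: minutes only anchor the calendar; features
# are supplied precomputed so the heavy extraction is skipped
make_record <- function(n_days = 190, vqids = 8, gad = 8, visit_every = 60,
                        madrs = rep(6, 3), seed = 1) {
  set.seed(seed)
  enr <- as.Date("2022-01-03")
  counts <- matrix(rpois(n_days * 1440, 20), n_days, 1440)
  ms <- minute_series("X1", enr + seq_len(n_days) - 1, counts)
  weeks <- 0:(n_days %/% 7 - 1)
  surveys <- data.frame(week = weeks, vqids_sr5 = vqids, gad7 = gad)
  vdays <- seq(visit_every, n_days - 1, by = visit_every)
  visits <- data.frame(date = enr + vdays, madrs = madrs[seq_along(vdays)],
                       cgis = 2, baseline_cgis = 2,
                       verification_madrs = NA_real_,
                       hospitalization = FALSE, suicidality = FALSE,
                       med_change_within_14d = FALSE,
                       investigator_decision = FALSE)
  patient_record("X1", ms, surveys, visits, enr)
}

iid_features <- function(n_days, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n_days * 8), n_days, 8)
  colnames(x) <- paste0("f", 1:8)
  x
}

# minimal visit row for label_visit tests
visit_row <- function(madrs, ver = NA, cgis = NA, baseline = NA, med = NA,
                      hosp = FALSE, suic = FALSE, inv = FALSE) {
  list(madrs = madrs, verification_madrs = ver, cgis = cgis,
       baseline_cgis = baseline, med_change_within_14d = med,
       hospitalization = hosp, suicidality = suic,
       investigator_decision = inv)
}
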