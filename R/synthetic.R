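#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study design the framework targets: one year of
#' follow-up, bimonthly clinic visits, a two-month relapse-free lead-in,
#' healthy activity with strong long-range correlation (DFA alpha near 1)
#' that degrades toward uncorrelated, low-amplitude, more monotonous
#' activity during the prodrome and relapse, and weekly self-reports that
#' track the latent severity.
#'
#' @param n_patients Cohort size.
#' @param follow_up_days Days from enrollment to the last scheduled visit.
#' @param relapse_fraction Probability that a patient relapses during
#'   follow-up.
#' @param visit_interval_days Days between clinic visits.
#' @param lead_in_clean_days Relapse-free lead-in before the first visit;
#'   at least 60 days (the framework's initial-training requirement).
#' @param alpha_target_healthy,alpha_target_relapse DFA scaling exponents
#'   the generator aims at in each regime (recovered via the Hurst index of
#'   the fractional Gaussian noise driving the counts).
#' @param entropy_scale_healthy,entropy_scale_relapse Amplitude scale per
#'   regime; lowering it flattens and quantizes the counts, which lowers
#'   sample entropy (more monotonous activity).
#' @param mesor,amplitude Circadian gate (counts/min): daily mean level and
#'   peak-to-mesor swing, peaking mid-afternoon.
#' @param noise_sigma Log-scale multiplicative noise intensity.
#' @param survey_noise_sd SD of the noise added to the survey severity map.
#' @param missing_minute_rate Expected fraction of minutes lost to device
#'   non-wear (injected as short runs).
#' @param spike_rate Per-minute probability of an artifact spike.
#' @param zero_run_rate Per-day probability of an injected long zero run
#'   (> 60 min, i.e. a flaggable gap).
#' @param prodrome_days Range (min, max) of days the severity ramp starts
#'   before relapse onset.
#' @param seed Master seed; per-patient and per-day streams are derived
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20, follow_up_days = 365,
                       relapse_fraction = 0.3, visit_interval_days = 60,
                       lead_in_clean_days = 60,
                       alpha_target_healthy = 0.95,
                       alpha_target_relapse = 0.65,
                       entropy_scale_healthy = 1,
                       entropy_scale_relapse = 0.35,
                       mesor = 150, amplitude = 120, noise_sigma = 0.5,
                       survey_noise_sd = 1,
                       missing_minute_rate = 0.005, spike_rate = 5e-5,
                       zero_run_rate = 0.02, prodrome_days = c(14, 28),
                       seed = 1) {
  stopifnot(relapse_fraction >= 0, relapse_fraction <= 1,
            missing_minute_rate >= 0, missing_minute_rate <= 1,
            spike_rate >= 0, spike_rate <= 1,
            zero_run_rate >= 0, zero_run_rate <= 1,
            alpha_target_healthy > 0.4, alpha_target_healthy < 1.2,
            alpha_target_relapse > 0.4, alpha_target_relapse < 1.2,
            lead_in_clean_days >= 60)
  structure(as.list(environment()), class = "sim_config")
}

#' Latent severity trajectory for one synthetic patient
#'
#' Stands in for the unobservable disease state: severity `s(t)` in `[0, 1]`
#' per day. Healthy patients stay at zero; relapsing patients follow a
#' bounded upward random walk starting 2-4 weeks before onset (the
#' detectable prodrome) and remain severe from onset on.
#'
#' @param n_days Length of follow-up in days.
#' @param onset_day Relapse onset as a 0-based day offset, or `NULL` for a
#'   patient who never relapses.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return An object of class `latent_trajectory`: data frame with `day`
#'   (0-based offset), `severity`, `regime`
#'   (`healthy`/`prodrome`/`relapse`).
#' @export
latent_trajectory <- function(n_days, onset_day = NULL,
                              config = sim_config(), seed = 1) {
  set.seed(seed)
  s <- numeric(n_days)
  regime <- rep("healthy", n_days)
  if (!is.null(onset_day)) {
    len <- sample(seq(config$prodrome_days[1], config$prodrome_days[2]), 1)
    start <- max(0L, onset_day - len)
    ramp_idx <- which(seq_len(n_days) - 1L >= start &
                        seq_len(n_days) - 1L < onset_day)
    if (length(ramp_idx)) {
      steps <- rnorm(length(ramp_idx), mean = 1 / length(ramp_idx), sd = 0.03)
      s[ramp_idx] <- pmin(1, pmax(0, cumsum(steps)))
      regime[ramp_idx] <- "prodrome"
    }
    rel_idx <- which(seq_len(n_days) - 1L >= onset_day)
    s[rel_idx] <- runif(length(rel_idx), 0.93, 1)
    regime[rel_idx] <- "relapse"
  }
  structure(data.frame(day = seq_len(n_days) - 1L, severity = s,
                       regime = regime),
            class = c("latent_trajectory", "data.frame"))
}

#' Simulate minute-resolution activity counts from a severity trajectory
#'
#' Counts follow `round(max(0, gate(t) * exp(sigma * g(t))))` where `gate`
#' is a cosine circadian profile peaking mid-afternoon and `g` is
#' fractional Gaussian noise whose Hurst index interpolates between the
#' healthy and relapse scaling targets with severity; severity also shrinks
#' the gate amplitude (the entropy knob). Device non-wear runs, long zero
#' runs and amplitude spikes are injected at the configured rates. One
#' seeded noise stream per day makes the record reproducible and
#' day-parallel.
#'
#' @param trajectory A [latent_trajectory()].
#' @param config A [sim_config()].
#' @param seed Patient-level seed (day streams derive from it).
#' @param enrollment Calendar date of day 0.
#' @param patient_id Identifier stored in the series.
#' @return A [minute_series()].
#' @export
simulate_minute_counts <- function(trajectory, config = sim_config(),
                                   seed = 1, enrollment = as.Date("2020-01-06"),
                                   patient_id = "sim") {
  n_days <- nrow(trajectory)
  set.seed(seed)
  day_seeds <- sample.int(.Machine$integer.max - 1L, n_days)
  minute <- 0:1439
  gate0 <- config$mesor + config$amplitude * cos(2 * pi * (minute - 900) / 1440)
  gate0 <- pmax(gate0, 0)
  counts <- matrix(NA_real_, n_days, 1440L)
  for (d in seq_len(n_days)) {
    set.seed(day_seeds[d])
    sev <- trajectory$severity[d]
    H <- config$alpha_target_healthy +
      sev * (config$alpha_target_relapse - config$alpha_target_healthy)
    H <- min(max(H, 0.05), 0.98)
    amp <- 1 + sev * (config$entropy_scale_relapse / config$entropy_scale_healthy - 1)
    g <- fgn_sim(1440L, H)
    x <- round(pmax(0, gate0 * config$entropy_scale_healthy * amp *
                      exp(config$noise_sigma * g)))
    # artifact spikes
    sp <- runif(1440L) < config$spike_rate
    x[sp] <- 40 * (config$mesor + config$amplitude)
    # injected long zero run (> 60 min, a flaggable gap)
    if (runif(1) < config$zero_run_rate) {
      len <- 61L + stats::rgeom(1, 1 / 60)
      at <- sample.int(1440L - len, 1)
      x[at:(at + len - 1L)] <- 0
    }
    # device non-wear: short missing runs totalling ~missing_minute_rate
    n_runs <- stats::rpois(1, config$missing_minute_rate * 1440 / 20)
    for (k in seq_len(n_runs)) {
      len <- 1L + stats::rgeom(1, 1 / 20)
      at <- sample.int(1440L, 1)
      x[at:min(1440L, at + len - 1L)] <- NA_real_
    }
    counts[d, ] <- x
  }
  minute_series(patient_id, enrollment + (seq_len(n_days) - 1L), counts)
}

#' Simulate weekly self-report surveys from a severity trajectory
#'
#' Weekly scores are a clipped, rounded monotone map of the mean weekly
#' severity plus Gaussian noise: zero severity maps below both mild bands,
#' full severity maps into the moderate-to-severe range of both
#' instruments.
#'
#' @inheritParams simulate_minute_counts
#' @return Data frame with `week`, `vqids_sr5`, `gad7`.
#' @export
simulate_surveys <- function(trajectory, config = sim_config(), seed = 1) {
  set.seed(seed)
  n_weeks <- nrow(trajectory) %/% 7L
  out <- data.frame(week = seq_len(n_weeks) - 1L, vqids_sr5 = NA_real_,
                    gad7 = NA_real_)
  for (w in seq_len(n_weeks)) {
    idx <- which(trajectory$day >= 7 * (w - 1L) & trajectory$day < 7 * w)
    sbar <- mean(trajectory$severity[idx])
    out$vqids_sr5[w] <- min(15, max(0, round(2 + 5.5 * sbar +
                                               rnorm(1, 0, config$survey_noise_sd))))
    out$gad7[w] <- min(21, max(0, round(2 + 10 * sbar +
                                          rnorm(1, 0, config$survey_noise_sd))))
  }
  out
}

#' Simulate a labeled synthetic cohort
#'
#' Generates complete [patient_record()]s: a clean lead-in, bimonthly
#' visits, weekly surveys, and for relapsing patients a relapse onset whose
#' clinician-rated severity proxy crosses the MADRS 22 threshold with
#' verification persistence. Records are truncated at the first relapse
#' visit; everyone else is followed through the last scheduled visit. The
#' clinician proxy is a saturating linear map of severity calibrated so
#' that healthy visits sit well below the enrollment ceiling (MADRS <= 14)
#' and relapse visits cross 22.
#'
#' @param config A [sim_config()].
#' @param enrollment Calendar date of day 0 for every patient.
#' @return A list of `patient_record`s with attribute `truth`: data frame
#'   of `patient_id`, `relapse`, `onset_day` (0-based offset or `NA`).
#' @export
simulate_cohort <- function(config = sim_config(),
                            enrollment = as.Date("2020-01-06")) {
  visit_days <- seq(config$lead_in_clean_days, config$follow_up_days,
                    by = config$visit_interval_days)
  if (length(visit_days) < 3L)
    stop("infeasible config: need at least 3 scheduled visits ",
         "(lengthen follow_up_days)")
  set.seed(config$seed)
  pat_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 3L * config$n_patients),
                      ncol = 3L)
  relapse <- rbinom(config$n_patients, 1, config$relapse_fraction) == 1
  madrs_noise_seeds <- sample.int(.Machine$integer.max - 1L, config$n_patients)

  records <- vector("list", config$n_patients)
  truth <- data.frame(patient_id = sprintf("P%03d", seq_len(config$n_patients)),
                      relapse = relapse, onset_day = NA_integer_)
  for (i in seq_len(config$n_patients)) {
    pid <- truth$patient_id[i]
    set.seed(pat_seeds[i, 1])
    if (relapse[i]) {
      # relapse visit drawn from the visits with room for a clean lead-in
      v <- sample(3:length(visit_days), 1)
      onset <- visit_days[v] - sample(7:35, 1)
      last_day <- visit_days[v]
      kept_visits <- visit_days[1:v]
      truth$onset_day[i] <- onset
    } else {
      onset <- NULL
      last_day <- visit_days[length(visit_days)]
      kept_visits <- visit_days
    }
    n_days <- last_day + 1L
    traj <- latent_trajectory(n_days, onset, config, seed = pat_seeds[i, 1])
    minutes <- simulate_minute_counts(traj, config, seed = pat_seeds[i, 2],
                                      enrollment = enrollment,
                                      patient_id = pid)
    surveys <- simulate_surveys(traj, config, seed = pat_seeds[i, 3])

    set.seed(madrs_noise_seeds[i])
    sev_at <- function(day) traj$severity[pmin(day, n_days - 1L) + 1L]
    madrs <- round(pmin(60, 6 + 20 * sev_at(kept_visits) +
                          rnorm(length(kept_visits), 0, 0.8)))
    ver <- rep(NA_real_, length(kept_visits))
    rel_v <- if (relapse[i]) length(kept_visits) else 0L
    if (rel_v > 0) {
      madrs[rel_v] <- max(madrs[rel_v], 22)
      ver[rel_v] <- max(22, round(6 + 20 * sev_at(kept_visits[rel_v] + 10L)))
    }
    visits <- data.frame(
      date = enrollment + kept_visits,
      madrs = madrs,
      cgis = pmin(7, pmax(1, 2 + round(4 * sev_at(kept_visits)))),
      baseline_cgis = 2,
      verification_madrs = ver,
      hospitalization = FALSE, suicidality = FALSE,
      med_change_within_14d = FALSE, investigator_decision = FALSE)
    visits$label <- vapply(seq_len(nrow(visits)),
                           function(k) label_visit(visits[k, ]), character(1))
    if (relapse[i] && visits$label[nrow(visits)] != "relapse")
      stop("internal: constructed relapse visit failed its own criteria")
    records[[i]] <- patient_record(pid, minutes, surveys, visits, enrollment)
  }
  attr(records, "truth") <- truth
  records
}
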