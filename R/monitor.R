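#' Bundle one patient's longitudinal data
#'
#' The N-of-1 unit: continuous minute-level activity, weekly self-reports
#' and labeled bimonthly clinic visits for a single patient.
#'
#' @param patient_id Identifier.
#' @param minutes A [minute_series()].
#' @param surveys Data frame with columns `week` (integer index from
#'   enrollment), `vqids_sr5`, `gad7` (`NA` = not completed).
#' @param visits Data frame with one row per clinic visit: `date`, `madrs`,
#'   `cgis`, `baseline_cgis`, `verification_madrs`, `hospitalization`,
#'   `suicidality`, `med_change_within_14d`, `investigator_decision`, and
#'   optionally a precomputed `label`.
#' @param enrollment Enrollment date (`Date`); anchors the weekly survey
#'   schedule.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, minutes, surveys, visits, enrollment) {
  stopifnot(inherits(minutes, "minute_series"))
  visits$date <- as.Date(visits$date)
  visits <- visits[order(visits$date), , drop = FALSE]
  structure(list(patient_id = patient_id, minutes = minutes,
                 surveys = surveys, visits = visits,
                 enrollment = as.Date(enrollment)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "-", nrow(x$visits), "visits,",
      nrow(x$surveys), "weekly surveys,", length(x$minutes$days),
      "days of activity\n")
  invisible(x)
}

#' Configuration of the relapse-monitoring pipeline
#'
#' @param hidden_size,epochs,lr,window,val_frac,patience Passed to
#'   [encdec_ad()].
#' @param retrain_epochs Epoch budget for warm-start retraining after each
#'   non-relapse visit.
#' @param retrain `"warm"` continues from the previous weights; `"scratch"`
#'   refits from a fresh initialization.
#' @param seed Base RNG seed.
#' @param ewma_span,z_grid,prune_p Passed to
#'   [detect_anomalous_instances()].
#' @param ridge_cond Error-covariance conditioning ceiling.
#' @param mild_rule Passed to [assess_exacerbation()].
#' @param min_lead_in Minimum relapse-free lead-in (days) required before
#'   the first evaluated visit.
#' @param criteria An [exacerbation_criteria()].
#' @param quality A [quality_params()].
#' @param saen A [saen_params()].
#' @param scales Fluctuation-analysis scales.
#' @return An object of class `nof1_config`.
#' @export
nof1_config <- function(hidden_size = 32, epochs = 150, retrain_epochs = 60,
                        retrain = c("warm", "scratch"), lr = 0.01, seed = 1,
                        window = 14, val_frac = 0.2, patience = 15,
                        ewma_span = 7, z_grid = seq(2, 10, by = 0.5),
                        prune_p = 0.13, ridge_cond = 1e8,
                        mild_rule = "cross_instrument", min_lead_in = 60,
                        criteria = exacerbation_criteria(),
                        quality = quality_params(), saen = saen_params(),
                        scales = dfa_scales()) {
  structure(list(hidden_size = hidden_size, epochs = epochs,
                 retrain_epochs = retrain_epochs,
                 retrain = match.arg(retrain), lr = lr, seed = seed,
                 window = window, val_frac = val_frac, patience = patience,
                 ewma_span = ewma_span, z_grid = z_grid, prune_p = prune_p,
                 ridge_cond = ridge_cond, mild_rule = mild_rule,
                 min_lead_in = min_lead_in, criteria = criteria,
                 quality = quality, saen = saen, scales = scales),
            class = "nof1_config")
}

# weeks whose days intersect the date span (a, b]
.weeks_in_interval <- function(from, to, anchor) {
  days <- seq(from + 1, to, by = "day")
  sort(unique(as.integer(floor(as.numeric(days - anchor) / 7))))
}

#' Run the continuous relapse-prediction protocol on one patient
#'
#' Implements the visit-by-visit protocol: an initial model is trained on
#' the relapse-free lead-in (enrollment to first clinic visit), each
#' subsequent inter-visit interval is scored day by day, anomalous
#' instances are detected with the adaptive threshold, aligned to weeks and
#' confirmed against the weekly surveys; the first confirmed week raises a
#' relapse flag and suspends prediction until the next visit. After every
#' non-relapse visit the model is retrained on the grown relapse-free
#' history. Follow-up is truncated at the first relapse visit. The
#' `"active_only"` comparator applies the survey criterion every week and
#' never consults the activity stream.
#'
#' @param record A [patient_record()].
#' @param mode `"passive_active"` (default) or `"active_only"`.
#' @param config A [nof1_config()].
#' @param features Optional precomputed [feature_table()] for the record
#'   (rows must align with `record$minutes$days`); computed when `NULL`.
#' @param mask Optional precomputed [detect_gaps()] result.
#' @return An object of class `nof1_run`: per-visit predictions, flag
#'   events, lead times, burden accounting and the score trace.
#' @export
nof1_run <- function(record, mode = c("passive_active", "active_only"),
                     config = nof1_config(), features = NULL, mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "patient_record"))
  visits <- record$visits
  if (is.null(visits$label))
    visits$label <- vapply(seq_len(nrow(visits)),
                           function(i) label_visit(visits[i, ]), character(1))
  # truncate at the first relapse
  first_rel <- which(visits$label == "relapse")[1]
  if (!is.na(first_rel)) visits <- visits[seq_len(first_rel), , drop = FALSE]
  if (nrow(visits) < 2L)
    stop("need at least two clinic visits (lead-in visit plus one evaluated visit)")
  lead_in <- as.numeric(visits$date[1] - record$enrollment)
  if (lead_in < config$min_lead_in)
    stop("patient excluded: relapse-free lead-in of ", lead_in,
         " days is shorter than ", config$min_lead_in)

  days <- record$minutes$days
  need_passive <- mode == "passive_active"
  if (need_passive) {
    if (is.null(features)) {
      if (is.null(mask)) mask <- detect_gaps(record$minutes, config$quality)
      features <- feature_table(record$minutes, mask, params = config$quality,
                                saen = config$saen, scales = config$scales)
    }
    fmat <- .as_feature_matrix(features)
    if (nrow(fmat) != length(days))
      stop("`features` must have one row per day of the minute series")
  }

  model <- NULL
  flags <- data.frame(week = integer(0), flag_date = as.Date(character(0)))
  trace <- data.frame(date = as.Date(character(0)), score = numeric(0),
                      is_instance = logical(0), daily_flag = logical(0))
  consulted_weeks <- integer(0)
  passive_weeks <- integer(0)
  train_sizes <- integer(0)
  n_models <- 0L

  if (need_passive) {
    tr_rows <- which(days <= visits$date[1])
    model <- encdec_ad(fmat[tr_rows, , drop = FALSE],
                       hidden_size = config$hidden_size,
                       epochs = config$epochs, lr = config$lr,
                       seed = config$seed, window = config$window,
                       val_frac = config$val_frac, patience = config$patience,
                       ridge_cond = config$ridge_cond)
    n_models <- 1L
    train_sizes <- length(tr_rows)
  }

  for (v in 2:nrow(visits)) {
    iv_days <- days[days > visits$date[v - 1] & days <= visits$date[v]]
    if (!length(iv_days)) next
    if (need_passive) {
      ctx_from <- iv_days[1] - (config$window - 1L)
      ctx_rows <- which(days >= ctx_from & days <= iv_days[length(iv_days)])
      E <- error_vectors(model, fmat[ctx_rows, , drop = FALSE])
      iv_pos <- match(iv_days, days[ctx_rows])
      sc <- anomaly_score(E[iv_pos, , drop = FALSE], model$error_model)
      sc[!is.finite(sc)] <- 0
      inst <- detect_anomalous_instances(sc, ewma_span = config$ewma_span,
                                         z_grid = config$z_grid,
                                         prune_p = config$prune_p,
                                         block = config$window)
      inst_days <- iv_days[inst]
      dl <- daily_anomaly_labels(inst_days, iv_days)
      wf <- weekly_flags(iv_days, dl, record$enrollment)
      trace <- rbind(trace, data.frame(date = iv_days, score = sc,
                                       is_instance = iv_days %in% inst_days,
                                       daily_flag = dl))
      cand_weeks <- wf$week[wf$flag]
      passive_weeks <- union(passive_weeks, cand_weeks)
    } else {
      cand_weeks <- .weeks_in_interval(visits$date[v - 1], visits$date[v],
                                       record$enrollment)
    }
    for (w in sort(cand_weeks)) {
      if (need_passive) consulted_weeks <- union(consulted_weeks, c(w, w + 1))
      if (assess_exacerbation(record$surveys, w, config$criteria,
                              config$mild_rule)) {
        fd <- record$enrollment + 7 * (w + 2) - 1  # confirming survey date
        flags <- rbind(flags, data.frame(week = w, flag_date = fd))
        break  # stop predicting until the next clinic visit
      }
    }
    if (need_passive && visits$label[v] == "non_relapse") {
      tr_rows <- which(days <= visits$date[v])
      model <- encdec_ad(fmat[tr_rows, , drop = FALSE],
                         hidden_size = config$hidden_size,
                         epochs = if (config$retrain == "warm")
                           config$retrain_epochs else config$epochs,
                         lr = config$lr, seed = config$seed + v,
                         window = config$window, val_frac = config$val_frac,
                         patience = config$patience,
                         ridge_cond = config$ridge_cond,
                         init = if (config$retrain == "warm") model)
      n_models <- n_models + 1L
      train_sizes <- c(train_sizes, length(tr_rows))
    }
  }

  # attribute each flag to the next scheduled visit on/after its date
  eval_visits <- visits[-1, , drop = FALSE]
  flags$visit <- as.Date(vapply(flags$flag_date, function(fd) {
    nx <- eval_visits$date[eval_visits$date >= fd]
    if (length(nx)) as.character(nx[1]) else NA_character_
  }, character(1)))
  flags <- flags[!is.na(flags$visit), , drop = FALSE]

  predictions <- data.frame(
    visit_date = eval_visits$date,
    label = eval_visits$label,
    predicted = eval_visits$date %in% flags$visit)
  tod <- numeric(0)
  for (i in which(predictions$predicted & predictions$label == "relapse")) {
    fd <- min(flags$flag_date[flags$visit == predictions$visit_date[i]])
    tod <- c(tod, time_of_detection(fd, predictions$visit_date[i]))
  }

  weeks_total <- .weeks_in_interval(visits$date[1],
                                    visits$date[nrow(visits)],
                                    record$enrollment)
  surveys_used <- if (mode == "active_only") length(weeks_total)
                  else min(length(consulted_weeks), length(weeks_total))

  structure(list(patient_id = record$patient_id, mode = mode,
                 predictions = predictions, flags = flags, tod = tod,
                 patient_days = as.numeric(visits$date[nrow(visits)] -
                                             visits$date[1]),
                 weekly_survey_slots = length(weeks_total),
                 surveys_used = surveys_used,
                 passive_weeks = sort(passive_weeks),
                 train_sizes = train_sizes,
                 trace = trace, model = model, n_models = n_models,
                 config = config),
            class = "nof1_run")
}

#' @export
print.nof1_run <- function(x, ...) {
  p <- x$predictions
  cat("<nof1_run>", x$patient_id, "(", x$mode, ")\n")
  cat("  ", nrow(p), "evaluated visits:",
      sum(p$label == "relapse"), "relapse /",
      sum(p$label == "non_relapse"), "non-relapse;",
      nrow(x$flags), "flag(s) raised\n")
  if (length(x$tod))
    cat("  time of detection (days):", paste(x$tod, collapse = ", "), "\n")
  invisible(x)
}
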