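#' Visit-level confusion counts
#'
#' @param predicted Logical vector: flag raised in the visit's interval.
#' @param label Character vector of visit labels (`"relapse"` /
#'   `"non_relapse"`); `NA` labels are an error.
#' @return An object of class `confusion_counts` with `TP`, `FP`, `TN`,
#'   `FN`, `total_visits`, `relapse_visits`, `nonrelapse_visits`.
#' @export
visit_confusion <- function(predicted, label) {
  if (length(predicted) != length(label))
    stop("`predicted` and `label` lengths differ")
  if (anyNA(label) || anyNA(predicted)) stop("unlabeled visit")
  if (!all(label %in% c("relapse", "non_relapse")))
    stop("labels must be 'relapse' or 'non_relapse'")
  rel <- label == "relapse"
  structure(list(TP = sum(predicted & rel), FN = sum(!predicted & rel),
                 FP = sum(predicted & !rel), TN = sum(!predicted & !rel),
                 total_visits = length(label),
                 relapse_visits = sum(rel),
                 nonrelapse_visits = sum(!rel)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$TP, " FP", x$FP, " TN", x$TN, " FN", x$FN,
      " (", x$relapse_visits, "relapse /", x$nonrelapse_visits,
      "non-relapse visits )\n")
  invisible(x)
}

.pct <- function(num, den) if (is.na(den) || den == 0) NA_real_ else 100 * num / den

#' Visit-level performance, burden and lead-time metrics
#'
#' Computes the full metric panel for a set of evaluated clinic visits:
#' sensitivity, specificity, balanced accuracy, predictive values, false
#' positive rate, false alarm rate (as a percentage of evaluated visits and
#' as alarms per patient-year), provider burden (preemptive visits, i.e.
#' `TP + FP`, per patient-year of observation), patient burden (share of
#' the weekly survey schedule actually administered) and the time of
#' detection. Rates use a 365-day year. Empty denominators give `NA`.
#'
#' @param counts A [visit_confusion()] result.
#' @param patient_days Total days of observation across patients.
#' @param surveys_used Number of weekly self-report assessments consulted.
#' @param weekly_survey_slots Number of scheduled weekly survey slots.
#' @param tod Vector of detection lead times (days) for true positives.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(counts, patient_days = NA_real_,
                            surveys_used = NA_real_,
                            weekly_survey_slots = NA_real_,
                            tod = numeric(0)) {
  stopifnot(inherits(counts, "confusion_counts"))
  sen <- .pct(counts$TP, counts$TP + counts$FN)
  spec <- .pct(counts$TN, counts$TN + counts$FP)
  out <- list(
    SEN = sen, SPEC = spec, BAC = (sen + spec) / 2,
    PPV = .pct(counts$TP, counts$TP + counts$FP),
    NPV = .pct(counts$TN, counts$TN + counts$FN),
    FPR = .pct(counts$FP, counts$FP + counts$TN),
    FAR_pct = .pct(counts$FP, counts$total_visits),
    FAR_rate = if (is.na(patient_days) || patient_days <= 0) NA_real_
               else 365 * counts$FP / patient_days,
    provider_burden = if (is.na(patient_days) || patient_days <= 0) NA_real_
                      else 365 * (counts$TP + counts$FP) / patient_days,
    patient_burden_pct = .pct(surveys_used, weekly_survey_slots),
    TOD_median = if (length(tod)) median(tod) else NA_real_,
    TOD_iqr = if (length(tod)) unname(quantile(tod, c(0.25, 0.75)))
              else c(NA_real_, NA_real_),
    tod = tod, counts = counts, patient_days = patient_days,
    surveys_used = surveys_used, weekly_survey_slots = weekly_survey_slots)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  f <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                 format = "f"))
  cat("Visit-level relapse prediction performance\n")
  cat(sprintf("  SEN %s%%  SPEC %s%%  BAC %s%%  PPV %s%%  NPV %s%%\n",
              f(x$SEN), f(x$SPEC), f(x$BAC), f(x$PPV), f(x$NPV)))
  cat(sprintf("  FPR %s%%  FAR %s%% (%s alarms/patient-year)\n",
              f(x$FPR), f(x$FAR_pct), formatC(x$FAR_rate, digits = 2,
                                              format = "f")))
  cat(sprintf("  provider burden %s preemptive visits/patient-year (%d over %s patient-days)\n",
              formatC(x$provider_burden, digits = 2, format = "f"),
              x$counts$TP + x$counts$FP, format(x$patient_days)))
  if (!is.na(x$patient_burden_pct))
    cat(sprintf("  patient burden %s%% of %s weekly surveys\n",
                f(x$patient_burden_pct), format(x$weekly_survey_slots)))
  if (length(x$tod))
    cat(sprintf("  time of detection: median %s days (IQR %s-%s)\n",
                format(x$TOD_median), format(x$TOD_iqr[1]),
                format(x$TOD_iqr[2])))
  invisible(x)
}

#' Detection lead time before a relapse visit
#'
#' Whole days between a raised flag and the relapse clinic visit it is
#' attributed to. A flag dated after its visit indicates an attribution
#' bug and is an error.
#'
#' @param flag_date,relapse_visit_date `Date`s (or numerics in days).
#' @return Days (non-negative).
#' @export
time_of_detection <- function(flag_date, relapse_visit_date) {
  d <- as.numeric(relapse_visit_date) - as.numeric(flag_date)
  if (any(d < 0)) stop("flag raised after the attributed visit")
  d
}

#' Aggregate per-patient runs into a cohort metrics report
#'
#' Pools visit-level predictions, observation time, survey accounting and
#' lead times across a list of [nof1_run()] results and summarizes them
#' with [compute_metrics()].
#'
#' @param runs List of `nof1_run` objects (one mode throughout).
#' @return A `metrics_report`.
#' @export
evaluate_cohort <- function(runs) {
  stopifnot(length(runs) > 0, all(vapply(runs, inherits, logical(1), "nof1_run")))
  pred <- do.call(rbind, lapply(runs, `[[`, "predictions"))
  counts <- visit_confusion(pred$predicted, pred$label)
  compute_metrics(counts,
                  patient_days = sum(vapply(runs, `[[`, numeric(1), "patient_days")),
                  surveys_used = sum(vapply(runs, `[[`, numeric(1), "surveys_used")),
                  weekly_survey_slots = sum(vapply(runs, `[[`, numeric(1),
                                                   "weekly_survey_slots")),
                  tod = unlist(lapply(runs, `[[`, "tod")))
}
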