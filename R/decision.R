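#' Symptom-exacerbation banding criteria
#'
#' Severity bands for the two weekly self-report instruments: the 5-item
#' very-quick depressive symptom inventory (VQIDS-SR5, range 0-15) and the
#' 7-item anxiety scale (GAD-7, range 0-21). Moderate-to-severe is VQIDS
#' >= 6 or GAD-7 >= 10; mild is VQIDS == 5 or 5 <= GAD-7 < 10.
#'
#' @param vqids_moderate,vqids_mild,gad_moderate,gad_mild_low Band edges.
#' @return An object of class `exacerbation_criteria`.
#' @export
exacerbation_criteria <- function(vqids_moderate = 6, vqids_mild = 5,
                                  gad_moderate = 10, gad_mild_low = 5) {
  stopifnot(vqids_moderate > vqids_mild, gad_moderate > gad_mild_low)
  structure(list(vqids_moderate = vqids_moderate, vqids_mild = vqids_mild,
                 gad_moderate = gad_moderate, gad_mild_low = gad_mild_low),
            class = "exacerbation_criteria")
}

#' Severity class of one self-report score
#'
#' @param instrument `"vqids"` or `"gad7"`.
#' @param score Integer total score (`NA` allowed, classed as `"none"`).
#' @param criteria An [exacerbation_criteria()].
#' @return `"none"`, `"mild"` or `"moderate_severe"`.
#' @export
severity_class <- function(instrument = c("vqids", "gad7"), score,
                           criteria = exacerbation_criteria()) {
  instrument <- match.arg(instrument)
  if (length(score) > 1L)
    return(vapply(score, function(s) severity_class(instrument, s, criteria),
                  character(1)))
  if (is.na(score)) return("none")
  rng <- if (instrument == "vqids") c(0, 15) else c(0, 21)
  if (score < rng[1] || score > rng[2])
    stop(instrument, " score ", score, " outside instrument range")
  if (instrument == "vqids") {
    if (score >= criteria$vqids_moderate) return("moderate_severe")
    if (score == criteria$vqids_mild) return("mild")
  } else {
    if (score >= criteria$gad_moderate) return("moderate_severe")
    if (score >= criteria$gad_mild_low) return("mild")
  }
  "none"
}

#' Assess symptom exacerbation over two consecutive weekly surveys
#'
#' Evaluates the two nearest consecutive surveys (the current week `w` and
#' the subsequent week `w + 1`). Exacerbation is present when (a) any of the
#' up to four observations (two instruments x two weeks) is
#' moderate-to-severe, or (b) the two-week window contains at least one mild
#' depressive score *and* one mild anxiety score (`mild_rule =
#' "cross_instrument"`, the default) / the same instrument is mild in both
#' weeks (`"same_instrument_both_weeks"`). Missing surveys are treated as
#' non-exacerbating.
#'
#' @param surveys Data frame with columns `week`, `vqids_sr5`, `gad7`.
#' @param week Index of the current week.
#' @param criteria An [exacerbation_criteria()].
#' @param mild_rule Reading of the two-mild-scores clause.
#' @return Logical.
#' @export
assess_exacerbation <- function(surveys, week,
                                criteria = exacerbation_criteria(),
                                mild_rule = c("cross_instrument",
                                              "same_instrument_both_weeks")) {
  mild_rule <- match.arg(mild_rule)
  get <- function(w, col) {
    v <- surveys[[col]][surveys$week == w]
    if (length(v)) v[1] else NA_real_
  }
  vq <- c(get(week, "vqids_sr5"), get(week + 1, "vqids_sr5"))
  gd <- c(get(week, "gad7"), get(week + 1, "gad7"))
  cv <- severity_class("vqids", vq, criteria)
  cg <- severity_class("gad7", gd, criteria)
  if (any(c(cv, cg) == "moderate_severe")) return(TRUE)
  if (mild_rule == "cross_instrument")
    any(cv == "mild") && any(cg == "mild")
  else
    all(cv == "mild") || all(cg == "mild")
}

#' Combine the passive and active criteria
#'
#' A relapse flag is raised if and only if a passive (actigraphy) anomaly
#' week is accompanied by self-reported symptom exacerbation.
#'
#' @param passive Logical weekly passive anomaly flag.
#' @param active Logical symptom-exacerbation assessment.
#' @return Logical.
#' @export
combined_decision <- function(passive, active) passive & active

#' Label a clinic visit as relapse or non-relapse
#'
#' A visit is a relapse when any of the pre-specified criteria holds:
#' MADRS >= 22 at the visit with worsening confirmed at a verification
#' visit (verification MADRS >= 22, or CGI-S change from baseline >= 2, or a
#' medication change within 14 days of the visit); or hospitalization for
#' worsening depression; or suicidal ideation with intent / suicidal
#' behavior; or investigator decision.
#'
#' @param visit A list or one-row data frame with fields `madrs`, `cgis`
#'   (CGI-S at the verification assessment), `baseline_cgis`,
#'   `verification_madrs`, `hospitalization`, `suicidality`,
#'   `med_change_within_14d`, `investigator_decision`. Event flags default
#'   to `FALSE` when absent; verification fields may be `NA` only when
#'   MADRS < 22.
#' @return `"relapse"` or `"non_relapse"`.
#' @export
label_visit <- function(visit) {
  g <- function(f, default = NA) {
    v <- visit[[f]]
    if (is.null(v) || length(v) == 0L) default else v[1]
  }
  madrs <- g("madrs")
  if (is.na(madrs)) stop("visit has no MADRS total score")
  hosp <- isTRUE(g("hospitalization", FALSE))
  suic <- isTRUE(g("suicidality", FALSE))
  inv <- isTRUE(g("investigator_decision", FALSE))
  if (hosp || suic || inv) return("relapse")
  if (madrs >= 22) {
    vm <- g("verification_madrs")
    cg <- g("cgis"); bg <- g("baseline_cgis")
    med <- g("med_change_within_14d")
    if (is.na(vm) && (is.na(cg) || is.na(bg)) && is.na(med))
      stop("MADRS >= 22 but no verification data: label unresolved")
    if (!is.na(vm) && vm >= 22) return("relapse")
    if (!is.na(cg) && !is.na(bg) && (cg - bg) >= 2) return("relapse")
    if (isTRUE(med)) return("relapse")
  }
  "non_relapse"
}
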