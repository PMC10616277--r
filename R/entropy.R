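#' Parameters for sample entropy
#'
#' @param m Template (embedding) length.
#' @param r Chebyshev tolerance. Increments are z-normalized before
#'   matching, so the default 0.2 corresponds to 20% of their standard
#'   deviation.
#' @param delta Time delay between template coordinates.
#' @return An object of class `saen_params`.
#' @export
saen_params <- function(m = 2, r = 0.2, delta = 1) {
  stopifnot(m >= 1, r > 0, delta >= 1)
  structure(list(m = as.integer(m), r = r, delta = as.integer(delta)),
            class = "saen_params")
}

#' Sample entropy of an activity series
#'
#' Computed on the z-normalized first difference of the counts (activity
#' series are long-range correlated; differencing yields an anti-correlated
#' process suited to entropy estimation). Template pairs of length `m` and
#' `m + 1` are counted with Chebyshev distance strictly below `r` at delay
#' `delta`, self-matches excluded, and `SaEn = -log(A/B)`. Lower values
#' indicate more regular, monotonous dynamics.
#'
#' @param x Numeric minute counts for one day or one 6-hour epoch, with no
#'   identified gaps (`NA` not allowed).
#' @param params A [saen_params()].
#' @return Sample entropy (non-negative), or `NA_real_` when no length-`m`
#'   template pair matches (undefined conditional probability).
#' @export
sample_entropy <- function(x, params = saen_params()) {
  stopifnot(inherits(params, "saen_params"))
  if (anyNA(x)) stop("`x` contains missing values; sample entropy requires a gap-free span")
  d <- diff(x)
  if (length(d) < params$m * params$delta + 1L)
    stop("series too short for the requested template length and delay")
  s <- sd(d)
  if (is.na(s) || s == 0)
    stop("degenerate input: increments have zero variance")
  z <- (d - mean(d)) / s
  cnt <- saen_counts(z, params$m, params$r, params$delta)
  if (cnt[["B"]] == 0) return(NA_real_)
  if (cnt[["A"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}
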