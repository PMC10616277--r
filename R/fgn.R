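#' Simulate fractional Gaussian noise
#'
#' Exact stationary simulation by circulant embedding (Davies-Harte): the
#' fGn autocovariance is embedded in a circulant matrix whose eigenvalues
#' are obtained by FFT, and a sample path is synthesized from complex
#' Gaussian spectral weights. For fGn the DFA scaling exponent equals the
#' Hurst index, which makes this the reference generator for exponent
#' recovery checks and for the synthetic activity model.
#'
#' @param n Series length.
#' @param H Hurst index in (0, 1).
#' @param sd Marginal standard deviation.
#' @return Numeric vector of length `n`; uses the R RNG, so results are
#'   reproducible under `set.seed()`.
#' @export
fgn_sim <- function(n, H, sd = 1) {
  stopifnot(n >= 1, H > 0, H < 1, sd > 0)
  if (H == 0.5) return(rnorm(n, sd = sd))
  acov <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                             abs(k - 1)^(2 * H))
  m <- 2^ceiling(log2(max(n, 2)))
  g <- acov(0:m)
  row1 <- c(g, g[m:2])                     # first row of the circulant, length 2m
  lam <- Re(fft(row1))
  lam[lam < 0] <- 0                        # clip tiny negative eigenvalues
  M <- 2L * m
  z <- complex(real = rnorm(M), imaginary = rnorm(M))
  w <- fft(sqrt(lam / M) * z)    # Re(w) carries the full target variance
  sd * Re(w)[seq_len(n)]
}
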