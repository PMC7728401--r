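## Imaging-noise variance from the high-frequency power spectrum.
##
## Above fs/4 the calcium signal (slow rise/decay transients) carries little
## power, so the spectrum there is dominated by the flat imaging-noise floor;
## averaging the PSD over (fs/4, fs/2) estimates the noise variance.

## Welch periodogram of one trace: Hann taper, 50% overlap, per-segment mean
## removal. Normalised so that for white noise of variance v the expected
## value at every (nonzero) Fourier frequency is v.
welchPsd <- function(x, fs, segLen = NULL) {
  Tt <- length(x)
  if (is.null(segLen)) segLen <- min(256L, floor(Tt / 4))
  segLen <- max(8L, as.integer(segLen))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLen) / segLen)  # periodic Hann
  U <- sum(w^2)
  step <- max(1L, segLen %/% 2L)
  starts <- seq.int(1L, Tt - segLen + 1L, by = step)
  acc <- numeric(segLen)
  for (s in starts) {
    xs <- x[s:(s + segLen - 1L)]
    xs <- xs - mean(xs)
    acc <- acc + Mod(stats::fft(xs * w))^2 / U
  }
  list(freq = (seq_len(segLen) - 1L) * fs / segLen, power = acc / length(starts))
}

#' Estimate per-neuron imaging-noise variance
#'
#' For each neuron, the noise variance is estimated as the mean of the Welch
#' power spectral density over frequencies strictly inside (fs/4, fs/2),
#' where the slow calcium transients contribute negligible power. The PSD is
#' normalised so the estimator is unbiased for white Gaussian noise: the
#' mean band power of noise with variance v is v.
#'
#' @param F a \linkS4class{FluorescenceSet} (or an N x T matrix if `fs` is
#'   given)
#' @param fs imaging rate, required when `F` is a bare matrix
#' @param segLen Welch segment length; default min(256, T/4)
#' @return list with `sigma2` (numeric N) and `band` = c(fs/4, fs/2)
#' @export
#' @examples
#' f <- FluorescenceSet(matrix(rnorm(2 * 512, sd = sqrt(0.1)), 2), fs = 2)
#' estimateNoiseVariance(f)$sigma2   # close to 0.1
estimateNoiseVariance <- function(F, fs = NULL, segLen = NULL) {
  if (is(F, "FluorescenceSet")) {
    fs <- F@fs
    Fm <- F@traces
  } else {
    Fm <- as.matrix(F)
    if (is.null(fs) || fs <= 0) stop("fs must be supplied and positive")
  }
  if (ncol(Fm) < 64) stop("need at least 64 frames for spectral estimation")
  sigma2 <- apply(Fm, 1, function(x) {
    p <- welchPsd(x, fs, segLen)
    band <- p$freq > fs / 4 & p$freq < fs / 2   # open interval, no endpoints
    mean(p$power[band])
  })
  list(sigma2 = as.numeric(sigma2), band = c(fs / 4, fs / 2))
}
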