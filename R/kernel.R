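#' Build a difference-of-exponentials calcium kernel
#'
#' Evaluates \eqn{k(t) = \exp(-t/\tau_d) - \exp(-t/\tau_r)} at integer frames
#' t = 0, 1, ... and truncates at the first frame past the peak where the
#' kernel falls below `truncationTol` times its maximum (or at `maxLen`).
#' The kernel is stored unnormalised; k(0) = 0 exactly.
#'
#' Time constants are in frame units. For a recording at rate `fs` Hz,
#' GCaMP6s defaults of 5.68/fs seconds rise and 11.5/fs seconds decay
#' correspond to `tauR = 5.68`, `tauD = 11.5` after dividing by `fs`
#' once — see [defaultKernel()] for the seconds-facing wrapper.
#'
#' @param tauR rise time constant (frames), 0 < tauR < tauD
#' @param tauD decay time constant (frames)
#' @param maxLen maximum kernel length in frames (>= 2)
#' @param truncationTol truncation threshold as a fraction of the peak
#' @return a \linkS4class{CalciumKernel}
#' @export
#' @examples
#' k <- makeKernel(5.68 / 2.1646, 11.5 / 2.1646)
#' kernelValues(k)[1]   # 0 at t = 0
makeKernel <- function(tauR, tauD, maxLen = 1000L, truncationTol = 1e-6) {
  if (!is.finite(tauR) || !is.finite(tauD) || tauR <= 0 || tauD <= 0)
    stop("time constants must be positive and finite")
  if (tauR >= tauD)
    stop("need tauR < tauD: the kernel must rise faster than it decays")
  if (maxLen < 2) stop("maxLen must be >= 2")
  t <- seq.int(0L, maxLen - 1L)
  v <- exp(-t / tauD) - exp(-t / tauR)
  v[1] <- 0                                  # exact, guards rounding
  pk <- which.max(v)
  below <- which(v < truncationTol * v[pk])
  below <- below[below > pk]
  if (length(below)) v <- v[seq_len(below[1] - 1L)]
  if (length(v) < 2) v <- c(0, exp(-1 / tauD) - exp(-1 / tauR))
  new("CalciumKernel", tauR = tauR, tauD = tauD, values = v,
      truncationTol = truncationTol)
}

#' Default calcium kernel for a given imaging rate
#'
#' Convenience wrapper converting the GCaMP6s constants 5.68 s rise and
#' 11.5 s decay into frame units via the imaging rate.
#'
#' @param fs imaging rate (Hz)
#' @param riseSec,decaySec time constants in seconds
#' @inheritParams makeKernel
#' @return a \linkS4class{CalciumKernel}
#' @export
defaultKernel <- function(fs, riseSec = 5.68, decaySec = 11.5,
                          maxLen = 1000L, truncationTol = 1e-6) {
  stopifnot2(fs > 0, "fs must be positive")
  makeKernel(riseSec / fs, decaySec / fs, maxLen = maxLen,
             truncationTol = truncationTol)
}

## Row-wise causal convolution of a Q x T matrix with a kernel vector,
## truncated to T frames: y[q, t] = sum_{tau <= t} k[t - tau] m[q, tau].
## Two paths: direct shift-and-add for short kernels, FFT above a length
## threshold; both agree to float tolerance (tested against a double loop).
convRowsCore <- function(k, M, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  M <- as.matrix(M)
  Tt <- ncol(M)
  Lk <- length(k)
  if (method == "auto") method <- if (Lk <= 128L) "direct" else "fft"
  if (method == "direct") {
    Y <- matrix(0, nrow(M), Tt)
    for (j in seq_len(min(Lk, Tt))) {      # j-1 is the kernel lag
      if (k[j] == 0) next
      Y[, j:Tt] <- Y[, j:Tt] + k[j] * M[, seq_len(Tt - j + 1L), drop = FALSE]
    }
    Y
  } else {
    n <- stats::nextn(Tt + Lk - 1L, 2)
    kf <- stats::fft(c(k, rep(0, n - Lk)))
    Mp <- cbind(M, matrix(0, nrow(M), n - Tt))
    Mf <- stats::mvfft(t(Mp))
    Y <- Re(stats::mvfft(Mf * kf, inverse = TRUE)) / n
    t(Y)[, seq_len(Tt), drop = FALSE]
  }
}

## Adjoint of convRowsCore: g[q, tau] = sum_{t >= tau} k[t - tau] m[q, t].
## Obtained by time-reversing, convolving causally, reversing back.
adjConvRows <- function(k, M) {
  M <- as.matrix(M)
  idx <- rev(seq_len(ncol(M)))
  convRowsCore(k, M[, idx, drop = FALSE])[, idx, drop = FALSE]
}

## Precomputed-FFT convolver for repeated convolutions with a fixed kernel
## and frame count (the optimiser inner loops). fwd is the causal
## convolution, adj its adjoint; both agree with convRowsCore/adjConvRows.
makeRowConvolver <- function(k, Tt) {
  Lk <- length(k)
  n <- stats::nextn(Tt + Lk - 1L, 2)
  kf <- stats::fft(c(k, rep(0, n - Lk)))
  pad <- function(M) rbind(t(M), matrix(0, n - Tt, nrow(M)))
  fwd <- function(M) {
    Y <- Re(stats::mvfft(stats::mvfft(pad(M)) * kf, inverse = TRUE)) / n
    t(Y[seq_len(Tt), , drop = FALSE])
  }
  list(fwd = fwd,
       adj = function(M) {
         idx <- rev(seq_len(Tt))
         fwd(M[, idx, drop = FALSE])[, idx, drop = FALSE]
       })
}

#' Causal convolution of intensity rows with a calcium kernel
#'
#' Computes, row by row, \eqn{c(t) = \sum_{\tau=0}^{t} k(t-\tau)
#' \lambda(\tau)}, truncated to the T frames of the input. The output at
#' frame t depends only on intensity at frames <= t, and the map is linear
#' in the intensity.
#'
#' @param kernel a \linkS4class{CalciumKernel}
#' @param intensity Q x T numeric matrix (or a vector, treated as one row)
#' @param method "auto" picks direct summation for short kernels and an
#'   FFT path for long ones; both give the same result
#' @return Q x T matrix of calcium concentrations
#' @export
convolveCausal <- function(kernel, intensity, method = "auto") {
  stopifnot2(is(kernel, "CalciumKernel"), "kernel must be a CalciumKernel")
  if (is.vector(intensity)) intensity <- matrix(intensity, nrow = 1)
  stopifnot2(all(is.finite(intensity)), "intensity must be finite")
  convRowsCore(kernel@values, intensity, method = method)
}
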