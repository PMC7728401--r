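## Penalised-regression estimation of the calcium transient time constants.
## tauD is parameterised as tauR + delta with delta > 0 so the rise is always
## faster than the decay. Alternates (a) per-neuron NNLS tuning curves given
## the current kernel with (b) bounded quasi-Newton descent on (tauR, delta)
## of the penalised reconstruction error, using the kernel's analytic
## derivatives.

## Kernel and its derivatives w.r.t. tauR and delta at frames 0..len-1.
## d k / d tauR = t/tauD^2 e^{-t/tauD} - t/tauR^2 e^{-t/tauR}
## d k / d delta = t/tauD^2 e^{-t/tauD}
## (verified against finite differences in the test suite)
kernelWithDerivs <- function(tauR, delta, len) {
  t <- seq.int(0L, len - 1L)
  tauD <- tauR + delta
  ed <- exp(-t / tauD)
  er <- exp(-t / tauR)
  list(k = ed - er,
       dTauR = t / tauD^2 * ed - t / tauR^2 * er,
       dDelta = t / tauD^2 * ed)
}

#' Estimate calcium transient time constants by penalised regression
#'
#' Alternates per-neuron NNLS estimation of tuning curves given the current
#' kernel with bounded minimisation of
#' \deqn{\tfrac12\sum_{n,t}(f_n(t) - (k_{\tau_r,\Delta} *
#' \omega_n^\top s)(t))^2 + \eta(\tau_r + \Delta)}
#' over \eqn{(\tau_r, \Delta)} using the kernel's analytic derivatives.
#' Typically only a few alternations are required. The rise constant is
#' clipped at 0.5 frames (with a warning) if the optimiser drives it to the
#' boundary.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param eta penalty weight on tauR + delta (> 0)
#' @param initTauR,initDelta starting values in frames
#' @param maxAlternations alternation cap
#' @param kernelLen evaluation length of the kernel in frames
#' @return list with `tauR`, `delta`, `tauD`, `eta`, `history`
#'   (objective per alternation) and `omega` (N x K tuning curves)
#' @export
estimateTimeConstants <- function(F, S, eta = 1, initTauR = 2,
                                  initDelta = 2, maxAlternations = 10L,
                                  kernelLen = NULL) {
  stopifnot2(eta > 0, "eta must be > 0")
  Fm <- F@traces; Sm <- S@design
  N <- nrow(Fm); Tt <- ncol(Fm); K <- nrow(Sm)
  if (is.null(kernelLen)) kernelLen <- min(Tt, 200L)
  tauR <- initTauR; delta <- initDelta
  history <- numeric(0)
  Omega <- matrix(0, N, K)
  lowerTauR <- 0.5
  for (it in seq_len(maxAlternations)) {
    kd <- kernelWithDerivs(tauR, delta, kernelLen)
    Phi <- convRowsCore(kd$k, Sm)
    C <- t(Phi)
    for (n in seq_len(N)) Omega[n, ] <- pracma::lsqnonneg(C, Fm[n, ])$x
    fn <- function(p) {
      kd <- kernelWithDerivs(p[1], p[2], kernelLen)
      R <- Fm - Omega %*% convRowsCore(kd$k, Sm)
      0.5 * sum(R^2) + eta * (p[1] + p[2])
    }
    gr <- function(p) {
      kd <- kernelWithDerivs(p[1], p[2], kernelLen)
      R <- Fm - Omega %*% convRowsCore(kd$k, Sm)
      dR <- Omega %*% convRowsCore(kd$dTauR, Sm)
      dD <- Omega %*% convRowsCore(kd$dDelta, Sm)
      c(-sum(R * dR) + eta, -sum(R * dD) + eta)
    }
    opt <- stats::optim(c(tauR, delta), fn, gr, method = "L-BFGS-B",
                        lower = c(lowerTauR, 0.1),
                        control = list(maxit = 200))
    tauR <- opt$par[1]; delta <- opt$par[2]
    history <- c(history, opt$value)
    if (tauR <= lowerTauR + 1e-9)
      warning("tauR reached its lower clip of ", lowerTauR, " frames")
    if (it > 1 && abs(history[it] - history[it - 1]) <
        1e-8 * (abs(history[it - 1]) + 1e-12)) break
  }
  list(tauR = tauR, delta = delta, tauD = tauR + delta, eta = eta,
       history = history, omega = Omega)
}
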