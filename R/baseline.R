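## Two-stage baseline for comparison: per-neuron NNLS regression onto
## stimulus regressors, then NMF on the rectified residuals. The NMF here is
## a compact Frobenius-objective solver (deterministic NNDSVD-a
## initialisation + multiplicative updates); only the objective and
## determinism matter for the comparison.

#' Stimulus regressors: kernel-convolved stimulus time series
#'
#' Row i is \eqn{\phi_i = k * s_i}, the calcium response expected from
#' stimulus i alone.
#'
#' @param S a \linkS4class{StimulusDesign}
#' @param kernel a \linkS4class{CalciumKernel}
#' @return K x T regressor matrix
#' @export
buildStimulusRegressors <- function(S, kernel) {
  convolveCausal(kernel, S@design)
}

#' Evoked component by per-neuron non-negative least squares
#'
#' Solves \eqn{\hat\beta_n = argmin_{\beta \ge 0} \|f_n - \beta^\top
#' \Phi\|^2} for each neuron and returns the implied evoked traces
#' \eqn{\hat\beta_n^\top \Phi}.
#'
#' @param F a \linkS4class{FluorescenceSet} (or bare N x T matrix)
#' @param Phi K x T regressor matrix from [buildStimulusRegressors()]
#' @return list with `betaStim` (N x K coefficients) and `evoked` (N x T)
#' @export
nnlsEvoked <- function(F, Phi) {
  Fm <- if (is(F, "FluorescenceSet")) F@traces else as.matrix(F)
  keep <- rowSums(abs(Phi)) > 0
  if (!all(keep)) warning("pruning ", sum(!keep), " all-zero regressor(s)")
  C <- t(Phi[keep, , drop = FALSE])
  if (qr(C)$rank < ncol(C))
    warning("stimulus regressors are rank-deficient / near-collinear")
  beta <- matrix(0, nrow(Fm), nrow(Phi))
  for (n in seq_len(nrow(Fm)))
    beta[n, keep] <- pracma::lsqnonneg(C, Fm[n, ])$x
  list(betaStim = beta, evoked = beta %*% Phi)
}

#' Rectified residuals
#'
#' Elementwise \eqn{\max(0, F - evoked)}: what the stimulus regression
#' leaves behind, clipped at zero so NMF applies.
#'
#' @param F a \linkS4class{FluorescenceSet} (or matrix)
#' @param evoked N x T evoked estimate
#' @return N x T non-negative matrix
#' @export
rectifiedResiduals <- function(F, evoked) {
  Fm <- if (is(F, "FluorescenceSet")) F@traces else as.matrix(F)
  if (!all(dim(Fm) == dim(evoked))) stop("shape mismatch")
  pmax(Fm - evoked, 0)
}

## NNDSVD-a initialisation (Boutsidis & Gallopoulos style): SVD-based,
## deterministic; zero entries filled with a small fraction of the mean.
nndsvdInit <- function(E, L) {
  sv <- svd(E, nu = L, nv = L)
  N <- nrow(E); Tt <- ncol(E)
  W <- matrix(0, N, L); H <- matrix(0, L, Tt)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (L > 1) for (j in 2:L) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npp >= nnn && npp > 0) {
      W[, j] <- sqrt(sv$d[j] * npp) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npp) * vp / sqrt(sum(vp^2))
    } else if (nnn > 0) {
      W[, j] <- sqrt(sv$d[j] * nnn) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nnn) * vn / sqrt(sum(vn^2))
    }
  }
  fill <- mean(E) / 100
  W[W <= 0] <- fill
  H[H <= 0] <- fill
  list(W = W, H = H)
}

#' Non-negative matrix factorisation of the rectified residuals
#'
#' Rank-L factorisation minimising \eqn{\|E - WH\|_F^2} with W, H >= 0:
#' deterministic NNDSVD-a initialisation followed by multiplicative
#' updates until the relative objective change falls below `tol` or
#' `maxIter` is reached. The spontaneous estimate for neuron n is
#' \eqn{W_n H}.
#'
#' @param E non-negative N x T residual matrix
#' @param L factorisation rank, 1 <= L <= min(N, T)
#' @param seed seed (reserved for the random fallback when E is degenerate;
#'   the default path is fully deterministic)
#' @param maxIter update cap
#' @param tol relative-change stopping tolerance on the objective
#' @return list with `W` (N x L), `H` (L x T), `spont` = W H, and
#'   `objective`, the squared-error trace
#' @export
nmfSpont <- function(E, L, seed = 1L, maxIter = 500L, tol = 1e-8) {
  E <- as.matrix(E)
  if (any(E < 0)) stop("E must be non-negative")
  if (L < 1 || L > min(dim(E))) stop("need 1 <= L <= min(N, T)")
  if (all(E == 0)) {
    W <- matrix(0, nrow(E), L); H <- matrix(0, L, ncol(E))
    return(list(W = W, H = H, spont = W %*% H, objective = 0))
  }
  ini <- nndsvdInit(E, L)
  W <- ini$W; H <- ini$H
  if (any(!is.finite(W)) || any(!is.finite(H))) {   # degenerate SVD fallback
    withSeed(seed, {
      W <- matrix(stats::runif(nrow(E) * L), ncol = L)
      H <- matrix(stats::runif(L * ncol(E)), nrow = L)
    })
  }
  eps <- .Machine$double.eps
  objective <- numeric(0)
  for (it in seq_len(maxIter)) {
    H <- H * (t(W) %*% E) / (t(W) %*% W %*% H + eps)
    W <- W * (E %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    obj <- sum((E - W %*% H)^2)
    objective <- c(objective, obj)
    if (it > 1 && abs(objective[it - 1] - obj) <
        tol * (objective[it - 1] + eps)) break
  }
  list(W = W, H = H, spont = W %*% H, objective = objective)
}

#' Express a spontaneous trace in a basis of calcium impulse responses
#'
#' NNLS of a trace onto T time-shifted copies of the calcium kernel (one
#' impulse response per frame). A trace that respects calcium-transient
#' structure is re-expressed with near-zero error; erratic components (e.g.
#' square pulses) leave a large normalised residual, reported as
#' `deviation` = ||trace - fit|| / ||trace||.
#'
#' @param spontTrace non-negative numeric vector (one trace)
#' @param kernel a \linkS4class{CalciumKernel}
#' @return list with `coef` (T non-negative coefficients), `fitted`, and
#'   `deviation`
#' @export
calciumBasisProjection <- function(spontTrace, kernel) {
  Tt <- length(spontTrace)
  Psi <- convRowsCore(kernel@values, diag(Tt))    # row t = k * delta_t
  sol <- pracma::lsqnonneg(t(Psi), as.numeric(spontTrace))
  fitted <- as.numeric(sol$x %*% Psi)
  nrm <- sqrt(sum(spontTrace^2))
  list(coef = sol$x, fitted = fitted,
       deviation = if (nrm > 0) sqrt(sum((spontTrace - fitted)^2)) / nrm
                   else 0)
}

#' Run the full residual-NMF baseline
#'
#' NNLS stimulus regression, residual rectification, and rank-L NMF, in one
#' call.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param L NMF rank
#' @param kernel a \linkS4class{CalciumKernel}
#' @param ... passed to [nmfSpont()]
#' @return list with `betaStim`, `evoked`, `residuals`, `W`, `H`, `spont`
#' @export
residualNmf <- function(F, S, L, kernel = defaultKernel(F@fs), ...) {
  Phi <- buildStimulusRegressors(S, kernel)
  ev <- nnlsEvoked(F, Phi)
  E <- rectifiedResiduals(F, ev$evoked)
  nm <- nmfSpont(E, L, ...)
  list(betaStim = ev$betaStim, evoked = ev$evoked, residuals = E,
       W = nm$W, H = nm$H, spont = nm$spont)
}
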