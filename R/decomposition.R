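## Post-fit analyses: evoked/spontaneous decomposition, variance components,
## drive ratios, private variability, factor contribution indices, tuning
## curves, shuffle nulls and factor cross-correlograms.

#' Decompose a fitted model into evoked and spontaneous traces
#'
#' \eqn{\hat f^{evoked}_n = \alpha_n k * w_n^\top s + \beta_n} and
#' \eqn{\hat f^{spont}_n = \alpha_n k * b_n^\top x + \beta_n}. Both
#' components include the baseline so that each aligns with the raw trace;
#' consequently evoked + spont - beta equals the full reconstruction.
#'
#' @param model a fitted \linkS4class{CilvaModel}
#' @param S the \linkS4class{StimulusDesign}
#' @param F optional \linkS4class{FluorescenceSet}; when given, the residual
#'   F - fhat is returned as well
#' @return list with `evoked`, `spont` and (when F is given) `residual`
#' @export
decomposeTraces <- function(model, S, F = NULL) {
  k <- model@kernel
  Sm <- S@design
  evoked <- model@alpha * convolveCausal(k, model@W %*% Sm) + model@beta
  L <- nrow(model@X)
  spontDrive <- if (L > 0) convolveCausal(k, model@B %*% model@X) else
    matrix(0, length(model@alpha), ncol(Sm))
  spont <- model@alpha * spontDrive + model@beta
  out <- list(evoked = evoked, spont = spont)
  if (!is.null(F))
    out$residual <- F@traces - (evoked + spont - model@beta)
  out
}

#' Per-neuron variance components of the reconstruction
#'
#' Sample variances over frames of the evoked and spontaneous components and
#' their covariance; the identity
#' var(fhat) = varE + varS + 2 covES holds exactly (baselines cancel).
#'
#' @param evoked,spont N x T component matrices from [decomposeTraces()]
#' @return list of numeric N vectors `varE`, `varS`, `covES`
#' @export
varianceComponents <- function(evoked, spont) {
  if (ncol(evoked) < 2) stop("need at least 2 frames")
  ce <- evoked - rowMeans(evoked)
  cs <- spont - rowMeans(spont)
  den <- ncol(evoked) - 1
  list(varE = rowSums(ce^2) / den,
       varS = rowSums(cs^2) / den,
       covES = rowSums(ce * cs) / den)
}

#' Drive ratio: evoked- vs spontaneous-dominance index
#'
#' \eqn{d_n = (var_E - var_S) / (var_E + var_S)}, in [-1, 1]; +1 for purely
#' evoked neurons, -1 for purely spontaneous ones. Undefined (NA) when both
#' variances are zero.
#'
#' @param varE,varS per-neuron component variances
#' @return numeric vector of drive ratios with NA where undefined
#' @export
driveRatio <- function(varE, varS) {
  tot <- varE + varS
  d <- ifelse(tot > 0, (varE - varS) / tot, NA_real_)
  as.numeric(d)
}

#' Noise-corrected variance and private-variability upper bound
#'
#' Corrects the raw sample variance for imaging noise
#' (varCorrected = var(f) - sigma2) and subtracts the reconstruction
#' variance to bound the private (unshared, unmodelled) variability:
#' priv = varCorrected - var(fhat). Negative values are reported as-is (and
#' flagged) — they diagnose noise-estimate error rather than true negative
#' variance.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param fhat N x T reconstruction
#' @param sigma2 per-neuron noise variances
#' @return list with `varCorrected`, `privateVar`, and logical `negative`
#'   flagging neurons with a negative bound
#' @export
correctedVariancePrivate <- function(F, fhat, sigma2) {
  vF <- apply(F@traces, 1, stats::var)
  vH <- apply(fhat, 1, stats::var)
  varCorrected <- vF - sigma2
  privateVar <- varCorrected - vH
  list(varCorrected = varCorrected, privateVar = privateVar,
       negative = privateVar < 0)
}

#' Factor contribution indices
#'
#' For each factor l, rebuilds the reconstruction with factor l deleted
#' (row l of X and column l of B removed) and reports
#' \eqn{1 - \frac1N \sum_n corr(f_n, \hat f^{(-l)}_n) / corr(f_n, \hat
#' f_n)}: the mean proportional drop in fit correlation when the factor is
#' removed. Neurons whose full-model correlation is within 1e-6 of zero are
#' excluded to avoid division blow-up.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param model a fitted \linkS4class{CilvaModel}
#' @param S the \linkS4class{StimulusDesign}
#' @return numeric vector of length L (empty when L = 0)
#' @export
factorContributionIndex <- function(F, model, S) {
  L <- nrow(model@X)
  if (L == 0) return(numeric(0))
  Fm <- F@traces
  fhat <- reconstruct(model, S)
  corFull <- vapply(seq_len(nrow(Fm)),
                    function(n) safeCor(Fm[n, ], fhat[n, ]), 0)
  keep <- is.finite(corFull) & abs(corFull) > 1e-6
  vapply(seq_len(L), function(l) {
    m <- CilvaModel(model@alpha, model@beta, model@W,
                    model@B[, -l, drop = FALSE],
                    model@X[-l, , drop = FALSE],
                    model@sigma2, model@gamma, model@kernel)
    fl <- reconstruct(m, S)
    r <- vapply(seq_len(nrow(Fm)), function(n) safeCor(Fm[n, ], fl[n, ]), 0)
    1 - mean(r[keep] / corFull[keep])
  }, 0)
}

#' Stimulus-onset frames of a design
#'
#' @param S a \linkS4class{StimulusDesign}
#' @return list of integer onset-frame vectors, one per stimulus
#' @export
stimulusOnsets <- function(S) {
  lapply(seq_len(nrow(S@design)), function(i) which(S@design[i, ] == 1))
}

#' Averaging-based tuning curves
#'
#' Classic estimate: for each neuron and stimulus, the mean dF/F over the
#' 4th to 7th frames after onset (offsets +4..+7 from the onset frame,
#' i.e. four frames), averaged over presentations. Onsets closer than 7
#' frames to the end of the recording are dropped with a warning; a
#' stimulus with no usable presentation gets NA.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign} (unshifted)
#' @return N x K matrix of tuning values
#' @export
averagedTuningCurve <- function(F, S) {
  Fm <- F@traces
  Tt <- ncol(Fm)
  onsets <- stimulusOnsets(S)
  out <- matrix(NA_real_, nrow(Fm), length(onsets))
  dropped <- 0L
  for (i in seq_along(onsets)) {
    os <- onsets[[i]]
    usable <- os[os + 7 <= Tt]
    dropped <- dropped + length(os) - length(usable)
    if (!length(usable)) next
    resp <- vapply(usable,
                   function(t0) rowMeans(Fm[, t0 + 4:7, drop = FALSE]),
                   numeric(nrow(Fm)))
    out[, i] <- rowMeans(matrix(resp, nrow = nrow(Fm)))
  }
  if (dropped > 0)
    warning("dropped ", dropped, " onset(s) within 7 frames of the end")
  if (any(colSums(!is.na(out)) == 0))
    warning("stimulus with zero usable presentations: column is NA")
  out
}

#' Model-based tuning curves
#'
#' \eqn{k_{max} \alpha_n w_n}: the stimulus filters rescaled by the kernel
#' peak and the neuron's amplitude, reporting evoked calcium-transient
#' amplitudes directly comparable with [averagedTuningCurve()].
#'
#' @param model a fitted \linkS4class{CilvaModel}
#' @return N x K matrix
#' @export
modelTuningCurve <- function(model) {
  max(model@kernel@values) * model@alpha * model@W
}

#' Cyclic-shuffle null distribution of a trace statistic
#'
#' Each shuffle cyclically permutes every row of `traceSet` by an
#' independent uniform random offset — preserving each trace's temporal
#' structure, mean and variance — and recomputes `statistic` on the shuffled
#' set. Used to calibrate fit correlations and evoked/spontaneous
#' covariances against chance.
#'
#' @param traceSet numeric matrix, traces as rows
#' @param statistic function taking the (shuffled) matrix, returning a
#'   numeric scalar or vector
#' @param nShuffles number of shuffles (>= 1)
#' @param seed integer seed; results are exactly reproducible
#' @return list with `values` (nShuffles x length(statistic) matrix) and
#'   `q95`, the per-component 95th percentile
#' @export
shuffleNull <- function(traceSet, statistic, nShuffles = 1000L, seed = 1L) {
  stopifnot2(nShuffles >= 1, "nShuffles must be >= 1")
  traceSet <- as.matrix(traceSet)
  Tt <- ncol(traceSet)
  p <- length(as.numeric(statistic(traceSet)))
  oneShuffle <- function(i) {
    off <- sample.int(Tt, nrow(traceSet), replace = TRUE) - 1L
    sh <- traceSet
    for (r in seq_len(nrow(sh)))
      if (off[r] > 0)
        sh[r, ] <- sh[r, c((Tt - off[r] + 1L):Tt, seq_len(Tt - off[r]))]
    as.numeric(statistic(sh))
  }
  vals <- withSeed(seed, t(vapply(seq_len(nShuffles), oneShuffle,
                                  numeric(p))))
  if (p == 1) vals <- matrix(as.numeric(vals), ncol = 1)
  list(values = vals, q95 = apply(vals, 2, stats::quantile, 0.95,
                                  names = FALSE))
}

#' Cross-correlograms between latent factors
#'
#' Normalised cross-correlation of mean-centred factor time series at lags
#' -maxLag..maxLag (zero-padded, so the diagonal at lag 0 is exactly 1).
#' Zero-variance factors are flagged with NA rows.
#'
#' @param X L x T factor activity matrix
#' @param maxLag maximum lag in frames
#' @return L x L x (2 maxLag + 1) array; `dimnames[[3]]` gives the lags
#' @export
factorCrossCorrelogram <- function(X, maxLag = 20L) {
  X <- as.matrix(X)
  L <- nrow(X); Tt <- ncol(X)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  lags <- -maxLag:maxLag
  out <- array(NA_real_, c(L, L, length(lags)),
               dimnames = list(NULL, NULL, lags))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (nrm[i] == 0 || nrm[j] == 0) next
    for (s in seq_along(lags)) {
      lg <- lags[s]
      if (lg >= 0) {
        a <- seq_len(Tt - lg); b <- a + lg
      } else {
        b <- seq_len(Tt + lg); a <- b - lg
      }
      out[i, j, s] <- sum(Xc[i, a] * Xc[j, b]) / (nrm[i] * nrm[j])
    }
  }
  out
}

#' Full post-fit decomposition of a recording
#'
#' Convenience wrapper assembling evoked/spontaneous/residual traces,
#' variance components, drive ratios, the private-variability bound and
#' factor contribution indices into a \linkS4class{CilvaDecomposition}.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param fit a \linkS4class{CilvaFit} (or a \linkS4class{CilvaModel})
#' @param S the \linkS4class{StimulusDesign}
#' @return a \linkS4class{CilvaDecomposition}
#' @export
cilvaDecompose <- function(F, fit, S) {
  model <- if (is(fit, "CilvaFit")) fit@model else fit
  dt <- decomposeTraces(model, S, F)
  vc <- varianceComponents(dt$evoked, dt$spont)
  fhat <- dt$evoked + dt$spont - model@beta
  pv <- correctedVariancePrivate(F, fhat, model@sigma2)
  new("CilvaDecomposition", evoked = dt$evoked, spont = dt$spont,
      residual = dt$residual, varEvoked = vc$varE, varSpont = vc$varS,
      covES = vc$covES, driveRatio = driveRatio(vc$varE, vc$varS),
      privateVar = pv$privateVar,
      contributionIndex = factorContributionIndex(F, model, S))
}

#' Per-neuron metrics table of a decomposition
#'
#' @param dec a \linkS4class{CilvaDecomposition}
#' @return data.frame with one row per neuron
#' @export
decompositionTable <- function(dec) {
  data.frame(neuron = seq_along(dec@varEvoked),
             varEvoked = dec@varEvoked, varSpont = dec@varSpont,
             covES = dec@covES, driveRatio = dec@driveRatio,
             privateVar = dec@privateVar)
}
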