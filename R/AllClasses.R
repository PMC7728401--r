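#' @import methods
NULL

#' CalciumKernel: discretised difference-of-exponentials impulse response
#'
#' Represents the stereotyped rise-and-decay waveform
#' \eqn{k(t) = \exp(-t/\tau_d) - \exp(-t/\tau_r)} that a unit burst of neural
#' activity imprints on a GCaMP fluorescence trace. Time constants are stored
#' in frame units; `values` holds the kernel evaluated at integer frames
#' 0, 1, ..., truncated once it falls below `truncationTol` of its peak.
#'
#' @slot tauR rise time constant (frames), 0 < tauR < tauD
#' @slot tauD decay time constant (frames)
#' @slot values numeric vector of kernel samples; values[1] = k(0) = 0
#' @slot truncationTol truncation threshold as a fraction of the peak
#' @exportClass CalciumKernel
setClass("CalciumKernel",
  representation(tauR = "numeric", tauD = "numeric", values = "numeric",
                 truncationTol = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@tauR) != 1 || !is.finite(object@tauR) ||
        object@tauR <= 0)
      msg <- c(msg, "tauR must be a single positive finite number")
    if (length(object@tauD) != 1 || !is.finite(object@tauD) ||
        object@tauD <= object@tauR)
      msg <- c(msg, "tauD must satisfy tauD > tauR > 0")
    if (length(object@values) < 2 || any(!is.finite(object@values)))
      msg <- c(msg, "kernel values must be finite with length >= 2")
    if (abs(object@values[1]) > 1e-12)
      msg <- c(msg, "k(0) must be 0")
    if (any(object@values < -1e-12))
      msg <- c(msg, "kernel values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' StimulusDesign: binary stimulus design matrix
#'
#' A K x T binary matrix whose row i is 1 at frames where stimulus i is
#' active (1-of-K encoding per frame unless the design has been expanded with
#' time-shifted copies of each stimulus, recorded by `shiftCount`).
#'
#' @slot design binary K x T matrix
#' @slot stimLabels character labels, one per row
#' @slot shiftCount number of single-frame shifted copies per stimulus
#' @exportClass StimulusDesign
setClass("StimulusDesign",
  representation(design = "matrix", stimLabels = "character",
                 shiftCount = "integer"),
  validity = function(object) {
    d <- object@design
    msg <- character(0)
    if (!all(d %in% c(0, 1)))
      msg <- c(msg, "design entries must be 0 or 1")
    if (length(object@stimLabels) != nrow(d))
      msg <- c(msg, "stimLabels length must equal nrow(design)")
    if (object@shiftCount < 0)
      msg <- c(msg, "shiftCount must be non-negative")
    if (object@shiftCount == 0 && nrow(d) > 0 && any(colSums(d) > 1))
      msg <- c(msg, "unshifted designs must be 1-of-K: at most one active stimulus per frame")
    if (length(msg)) msg else TRUE
  })

#' FluorescenceSet: observed dF/F traces with imaging rate
#'
#' Container for an N x T matrix of normalised fluorescence traces (dF/F,
#' unitless; negative entries are permitted, reflecting imaging noise) and
#' the imaging rate in Hz.
#'
#' @slot traces N x T numeric matrix, neurons as rows
#' @slot fs imaging rate (Hz)
#' @slot neuronIds character labels, one per neuron
#' @exportClass FluorescenceSet
setClass("FluorescenceSet",
  representation(traces = "matrix", fs = "numeric", neuronIds = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!all(is.finite(object@traces)))
      msg <- c(msg, "all trace entries must be finite")
    if (nrow(object@traces) < 1 || ncol(object@traces) < 2)
      msg <- c(msg, "need N >= 1 neurons and T >= 2 frames")
    if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@neuronIds) != nrow(object@traces))
      msg <- c(msg, "neuronIds length must equal the number of neurons")
    if (length(msg)) msg else TRUE
  })

#' CilvaModel: parameters and latent factors of the generative model
#'
#' Holds the full parameter set: per-neuron scale alpha and baseline beta,
#' N x K stimulus filters W, N x L factor couplings B, L x T non-negative
#' latent factor activity X, per-neuron imaging-noise variances sigma2, the
#' exponential-prior mean gamma and the calcium kernel. All of alpha, beta,
#' W, B, X are constrained non-negative; sigma2 strictly positive.
#'
#' @slot alpha numeric N, >= 0
#' @slot beta numeric N, >= 0
#' @slot W N x K matrix, >= 0
#' @slot B N x L matrix, >= 0 (L may be 0)
#' @slot X L x T matrix, >= 0
#' @slot sigma2 numeric N, > 0
#' @slot gamma exponential prior mean, > 0
#' @slot kernel CalciumKernel
#' @exportClass CilvaModel
setClass("CilvaModel",
  representation(alpha = "numeric", beta = "numeric", W = "matrix",
                 B = "matrix", X = "matrix", sigma2 = "numeric",
                 gamma = "numeric", kernel = "CalciumKernel"),
  validity = function(object) {
    msg <- character(0)
    N <- length(object@alpha)
    if (length(object@beta) != N || nrow(object@W) != N ||
        nrow(object@B) != N || length(object@sigma2) != N)
      msg <- c(msg, "alpha, beta, W, B, sigma2 must agree on N")
    if (ncol(object@B) != nrow(object@X))
      msg <- c(msg, "ncol(B) must equal nrow(X)")
    if (any(object@alpha < 0) || any(object@beta < 0) ||
        any(object@W < 0) || any(object@B < 0) || any(object@X < 0))
      msg <- c(msg, "alpha, beta, W, B, X must be non-negative")
    if (any(object@sigma2 <= 0))
      msg <- c(msg, "sigma2 must be strictly positive")
    if (length(object@gamma) != 1 || object@gamma <= 0)
      msg <- c(msg, "gamma must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' CilvaFit: a fitted model plus optimisation trace
#'
#' @slot model the fitted (standardised) CilvaModel
#' @slot objective penalised log-joint recorded after each alternation
#' @slot converged logical, TRUE if the relative-change criterion was met
#' @slot config list of fit settings (L, gamma, maxAlternations, tol, seed)
#' @exportClass CilvaFit
setClass("CilvaFit",
  representation(model = "CilvaModel", objective = "numeric",
                 converged = "logical", config = "list"))

#' CilvaDecomposition: per-neuron evoked/spontaneous decomposition
#'
#' @slot evoked N x T evoked component (includes the baseline)
#' @slot spont N x T shared-spontaneous component (includes the baseline)
#' @slot residual N x T residual F - fhat
#' @slot varEvoked,varSpont,covES per-neuron variance components
#' @slot driveRatio per-neuron index in [-1, 1]; NA where undefined
#' @slot privateVar per-neuron upper bound on private variance
#' @slot contributionIndex per-factor contribution index
#' @exportClass CilvaDecomposition
setClass("CilvaDecomposition",
  representation(evoked = "matrix", spont = "matrix", residual = "matrix",
                 varEvoked = "numeric", varSpont = "numeric",
                 covES = "numeric", driveRatio = "numeric",
                 privateVar = "numeric", contributionIndex = "numeric"))

## ---- constructors ----------------------------------------------------------

#' Construct a FluorescenceSet
#'
#' @param traces N x T numeric matrix of dF/F traces, neurons as rows
#' @param fs imaging rate in Hz
#' @param neuronIds optional neuron labels
#' @return a \linkS4class{FluorescenceSet}
#' @export
#' @examples
#' f <- FluorescenceSet(matrix(rnorm(20), 2, 10), fs = 2.1646)
#' nNeurons(f); nFrames(f)
FluorescenceSet <- function(traces, fs, neuronIds = NULL) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  if (is.null(neuronIds)) neuronIds <- paste0("n", seq_len(nrow(traces)))
  new("FluorescenceSet", traces = traces, fs = fs,
      neuronIds = as.character(neuronIds))
}

#' Construct a StimulusDesign from a binary matrix
#'
#' @param design binary K x T matrix (rows = stimuli)
#' @param stimLabels optional stimulus labels
#' @param shiftCount number of shifted copies already included (0 for a plain
#'   1-of-K design)
#' @return a \linkS4class{StimulusDesign}
#' @export
StimulusDesign <- function(design, stimLabels = NULL, shiftCount = 0L) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (is.null(stimLabels)) stimLabels <- paste0("s", seq_len(nrow(design)))
  new("StimulusDesign", design = design,
      stimLabels = as.character(stimLabels),
      shiftCount = as.integer(shiftCount))
}

#' Construct a CilvaModel
#'
#' @param alpha,beta numeric N vectors (scale and baseline)
#' @param W N x K stimulus filter matrix
#' @param B N x L coupling matrix
#' @param X L x T latent factor matrix
#' @param sigma2 numeric N noise variances
#' @param gamma exponential prior mean
#' @param kernel a \linkS4class{CalciumKernel}
#' @return a \linkS4class{CilvaModel}
#' @export
CilvaModel <- function(alpha, beta, W, B, X, sigma2, gamma, kernel) {
  new("CilvaModel", alpha = as.numeric(alpha), beta = as.numeric(beta),
      W = as.matrix(W), B = as.matrix(B), X = as.matrix(X),
      sigma2 = as.numeric(sigma2), gamma = gamma, kernel = kernel)
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "FluorescenceSet", function(object) {
  cat("FluorescenceSet:", nrow(object@traces), "neurons x",
      ncol(object@traces), "frames at", object@fs, "Hz\n")
})

setMethod("show", "StimulusDesign", function(object) {
  cat("StimulusDesign:", nrow(object@design), "stimuli x",
      ncol(object@design), "frames;", sum(object@design), "onsets",
      if (object@shiftCount > 0)
        paste0("(", object@shiftCount, " shifted copies)") else "", "\n")
})

setMethod("show", "CalciumKernel", function(object) {
  cat("CalciumKernel: tauR =", signif(object@tauR, 4), "frames, tauD =",
      signif(object@tauD, 4), "frames, length", length(object@values),
      "frames, peak", signif(max(object@values), 4), "\n")
})

setMethod("show", "CilvaModel", function(object) {
  cat("CilvaModel:", length(object@alpha), "neurons,",
      ncol(object@W), "stimuli,", nrow(object@X), "factors,",
      ncol(object@X), "frames; gamma =", object@gamma, "\n")
})

setMethod("show", "CilvaFit", function(object) {
  cat("CilvaFit:", length(object@objective), "alternations,",
      if (object@converged) "converged," else "not converged,",
      "final objective", signif(utils::tail(object@objective, 1), 8), "\n")
  show(object@model)
})

setMethod("show", "CilvaDecomposition", function(object) {
  cat("CilvaDecomposition:", nrow(object@evoked), "neurons x",
      ncol(object@evoked), "frames;",
      length(object@contributionIndex), "factors\n")
  dr <- object@driveRatio[is.finite(object@driveRatio)]
  if (length(dr))
    cat("  drive ratio: median", signif(stats::median(dr), 3), "\n")
})
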