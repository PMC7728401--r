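## Hyperparameter selection: gamma by grid search scored on held-out data,
## L guided by the elbow of the correlation-vs-L curve.

#' Split a recording into train and held-out test segments
#'
#' The test set is the final contiguous block of `round(testSeconds * fs)`
#' frames; the stimulus design is split identically. Contiguity means the
#' calcium autocorrelation is broken only once, at the boundary.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param testSeconds held-out duration in seconds (default 300, i.e. 5 min)
#' @return list with `trainF`, `trainS`, `testF`, `testS`, `nTest`;
#'   `testF`/`testS` are NULL when `nTest` is 0
#' @export
splitTrainTest <- function(F, S, testSeconds = 300) {
  Tt <- nFrames(F)
  nTest <- as.integer(round(testSeconds * F@fs))
  if (nTest >= Tt) stop("test segment must be shorter than the recording")
  if (nTest <= 0) {
    warning("empty test set: selection will fall back to the train objective")
    return(list(trainF = F, trainS = S, testF = NULL, testS = NULL,
                nTest = 0L))
  }
  tr <- seq_len(Tt - nTest)
  te <- (Tt - nTest + 1L):Tt
  list(trainF = FluorescenceSet(F@traces[, tr, drop = FALSE], F@fs,
                                F@neuronIds),
       trainS = StimulusDesign0(S@design[, tr, drop = FALSE]),
       testF = FluorescenceSet(F@traces[, te, drop = FALSE], F@fs,
                               F@neuronIds),
       testS = StimulusDesign0(S@design[, te, drop = FALSE]),
       nTest = nTest)
}

## Held-out score: log p(f_test | x_test, theta) p(x_test | gamma) with test
## latents inferred fresh under the candidate theta.
heldOutScore <- function(testF, testS, model, gamma, seed) {
  Xte <- inferLatents(testF, model, testS, gamma = gamma, seed = seed)
  m <- CilvaModel(model@alpha, model@beta, model@W, model@B, Xte,
                  model@sigma2, gamma, model@kernel)
  list(score = logJoint(testF, m, testS), Xtest = Xte)
}

#' Select sparsity and factor-count hyperparameters on held-out data
#'
#' For each factor count in `LList`, each gamma on the grid
#' `deltaGamma * (1..d)` and each of `iMax` random restarts, fits the model
#' on the training segment, infers fresh latents on the held-out segment,
#' and scores the held-out joint density. The winner maximises the held-out
#' score; its training latents are then re-inferred under the chosen
#' (theta, gamma).
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param LList integer vector of candidate factor counts
#' @param kernel a \linkS4class{CalciumKernel}
#' @param deltaGamma grid step (default 0.2)
#' @param d number of grid points (default 10)
#' @param iMax restarts per configuration (default 5)
#' @param testSeconds held-out duration (default 300 s)
#' @param sigma2 optional noise variances; estimated when NULL
#' @param seed base seed; restart i uses seed + i - 1
#' @param ... further arguments to [fitCilva()] (e.g. `maxAlternations`)
#' @return a selection report: list with `gammaGrid`, a `results`
#'   data.frame (L, gamma, restart, trainObjective, testScore), the chosen
#'   configuration, and `fit`, the winning \linkS4class{CilvaFit} with
#'   re-inferred training latents
#' @export
selectHyperparams <- function(F, S, LList, kernel = defaultKernel(F@fs),
                              deltaGamma = 0.2, d = 10L, iMax = 5L,
                              testSeconds = 300, sigma2 = NULL, seed = 1L,
                              ...) {
  grid <- deltaGamma * seq_len(d)
  if (is.null(sigma2)) sigma2 <- estimateNoiseVariance(F)$sigma2
  sp <- splitTrainTest(F, S, testSeconds)
  res <- NULL
  best <- NULL
  for (L in LList) for (g in grid) for (i in seq_len(iMax)) {
    fit <- fitCilva(sp$trainF, sp$trainS, L = L, gamma = g, kernel = kernel,
                    sigma2 = sigma2, seed = seed + i - 1L, restarts = 1L, ...)
    trainObj <- utils::tail(fit@objective, 1)
    score <- if (sp$nTest > 0)
      heldOutScore(sp$testF, sp$testS, fit@model, g, seed + i - 1L)$score
    else trainObj
    res <- rbind(res, data.frame(L = L, gamma = g, restart = i,
                                 trainObjective = trainObj,
                                 testScore = score))
    if (is.null(best) || score > best$score)
      best <- list(score = score, fit = fit, L = L, gamma = g, restart = i)
  }
  ## re-infer training latents under the selected (theta, gamma)
  finalX <- inferLatents(sp$trainF, best$fit@model, sp$trainS,
                         gamma = best$gamma, seed = seed + best$restart - 1L,
                         init = best$fit@model@X)
  m <- best$fit@model
  chosenModel <- CilvaModel(m@alpha, m@beta, m@W, m@B, finalX, m@sigma2,
                            best$gamma, m@kernel)
  fit <- new("CilvaFit", model = chosenModel,
             objective = best$fit@objective, converged = best$fit@converged,
             config = utils::modifyList(best$fit@config,
                                        list(gamma = best$gamma)))
  list(gammaGrid = grid, results = res,
       chosen = list(L = best$L, gamma = best$gamma, restart = best$restart,
                     testScore = best$score),
       fit = fit, split = sp)
}

#' Mean fit correlation as a function of the number of factors
#'
#' For each candidate L, fits the model on the training segment and reports
#' the mean over neurons of the Pearson correlation between trace and
#' reconstruction, on the training segment and on the held-out segment
#' (test reconstructions use freshly inferred test latents). Constant
#' traces, for which the correlation is undefined, are excluded with a
#' warning. The elbow of the resulting curve guides the choice of L.
#'
#' @inheritParams selectHyperparams
#' @param gamma sparsity prior mean used for every fit
#' @return data.frame with columns `L`, `trainCor`, `testCor`
#' @export
correlationVsL <- function(F, S, LList, gamma, kernel = defaultKernel(F@fs),
                           testSeconds = 300, sigma2 = NULL, seed = 1L,
                           ...) {
  if (is.null(sigma2)) sigma2 <- estimateNoiseVariance(F)$sigma2
  sp <- splitTrainTest(F, S, testSeconds)
  meanFitCor <- function(Fset, Sdes, model) {
    fhat <- reconstruct(model, Sdes)
    cc <- vapply(seq_len(nrow(fhat)),
                 function(n) safeCor(Fset@traces[n, ], fhat[n, ]), 0)
    if (anyNA(cc)) warning("excluding ", sum(is.na(cc)),
                           " neuron(s) with undefined correlation")
    finiteMean(cc)
  }
  out <- lapply(LList, function(L) {
    fit <- fitCilva(sp$trainF, sp$trainS, L = L, gamma = gamma,
                    kernel = kernel, sigma2 = sigma2, seed = seed, ...)
    trainCor <- meanFitCor(sp$trainF, sp$trainS, fit@model)
    testCor <- if (sp$nTest > 0) {
      Xte <- inferLatents(sp$testF, fit@model, sp$testS, seed = seed)
      m <- fit@model
      mTest <- CilvaModel(m@alpha, m@beta, m@W, m@B, Xte, m@sigma2,
                          m@gamma, m@kernel)
      meanFitCor(sp$testF, sp$testS, mTest)
    } else NA_real_
    data.frame(L = L, trainCor = trainCor, testCor = testCor)
  })
  do.call(rbind, out)
}
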