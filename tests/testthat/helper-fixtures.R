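# Shared fixtures and oracles, all built in code at test time.

## Literal double-loop transcription of the causal convolution
## c(t) = sum_{tau=0}^{t} k(t - tau) lambda(tau); the independent oracle for
## every convolution path.
convOracle <- function(k, M) {
  M <- as.matrix(M)
  Tt <- ncol(M)
  Y <- matrix(0, nrow(M), Tt)
  for (q in seq_len(nrow(M))) for (t in seq_len(Tt)) for (tau in seq_len(t)) {
    lag <- t - tau            # 0-based kernel index
    if (lag < length(k)) Y[q, t] <- Y[q, t] + k[lag + 1] * M[q, tau]
  }
  Y
}

## Small random valid model + matching design and data, deterministic.
randomInstance <- function(N = 3, K = 2, L = 2, Tt = 40, seed = 1,
                           gamma = 0.8) {
  set.seed(seed)
  kernel <- makeKernel(1.5, 4)
  design <- matrix(0, K, Tt)
  for (i in seq_len(K))
    design[i, sample(seq_len(Tt), max(1, Tt %/% 10))] <- 1
  design[, colSums(design) > 1] <- 0          # keep 1-of-K
  for (i in seq_len(K)) if (all(design[i, ] == 0)) design[i, i] <- 1
  S <- StimulusDesign(design)
  model <- CilvaModel(alpha = runif(N, 0.5, 2), beta = runif(N, 0, 0.3),
                      W = matrix(runif(N * K), N, K),
                      B = matrix(runif(N * L), N, L),
                      X = matrix(rexp(L * Tt) * rbinom(L * Tt, 1, 0.2), L, Tt),
                      sigma2 = runif(N, 0.05, 0.3), gamma = gamma,
                      kernel = kernel)
  F <- FluorescenceSet(reconstruct(model, S) +
                         matrix(rnorm(N * Tt, 0, 0.2), N, Tt), fs = 2)
  list(F = F, S = S, model = model)
}

## Central finite difference of logJoint along one coordinate of a model.
fdLogJoint <- function(F, model, S, slot, idx, h = 1e-6) {
  bump <- function(delta) {
    m <- model
    v <- slot(m, slot)
    v[idx] <- v[idx] + delta
    ## check = FALSE: central differences take tiny excursions below 0
    slot(m, slot, check = FALSE) <- v
    logJoint(F, m, S)
  }
  (bump(h) - bump(-h)) / (2 * h)
}

## Mean per-neuron Pearson correlation between two trace matrices.
meanRowCor <- function(A, B) {
  mean(vapply(seq_len(nrow(A)), function(n) cor(A[n, ], B[n, ]), 0))
}

## Evoked/spontaneous recovery of a fit against simulation ground truth.
recoveryStats <- function(sim, fit) {
  dec <- decomposeTraces(fittedModel(fit), sim$S)
  c(evoked = meanRowCor(sim$fEvokedTrue, dec$evoked),
    spont = meanRowCor(sim$fSpontTrue, dec$spont))
}

## Memoised heavy fits shared between acceptance blocks.
.fitCache <- new.env(parent = emptyenv())
cachedRecoveryFit <- function(simSeed, sigma2 = 0.1, pi = 0.05,
                              maxAlternations = 60) {
  key <- paste(simSeed, sigma2, pi, maxAlternations, sep = "_")
  if (is.null(.fitCache[[key]])) {
    sim <- simulateCilva(simulationConfig(seed = simSeed, sigma2 = sigma2,
                                          pi = pi))
    ns <- estimateNoiseVariance(sim$F)
    fit <- fitCilva(sim$F, sim$S, L = 3, gamma = 0.4, sigma2 = ns$sigma2,
                    maxAlternations = maxAlternations, seed = 0, maxit = 100)
    .fitCache[[key]] <- list(sim = sim, fit = fit,
                             recovery = recoveryStats(sim, fit))
  }
  .fitCache[[key]]
}
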