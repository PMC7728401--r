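makeEvokedOnly <- function(w = 2, Tt = 120, seed = 1) {
  kernel <- makeKernel(1.5, 4)
  design <- matrix(0, 1, Tt)
  design[1, c(10, 50, 90)] <- 1
  S <- StimulusDesign(design)
  phi <- convolveCausal(kernel, design)[1, ]
  list(S = S, kernel = kernel, phi = phi,
       F = FluorescenceSet(matrix(w * phi, 1), fs = 2))
}

test_that("NNLS initialisation solves exact and sign-flipped cases", {
  eo <- makeEvokedOnly(w = 2)
  m <- initParams(eo$F, eo$S, eo$kernel, L = 1, gamma = 1, sigma2 = 0.1,
                  seed = 1)
  expect_equal(as.numeric(m@W), 2, tolerance = 1e-8)
  expect_equal(m@beta, 0)
  ## non-negativity active for an anti-correlated trace
  Fneg <- FluorescenceSet(matrix(-eo$phi, 1), fs = 2)
  mNeg <- initParams(Fneg, eo$S, eo$kernel, L = 1, gamma = 1, sigma2 = 0.1,
                     seed = 1)
  expect_equal(as.numeric(mNeg@W), 0)
  ## deterministic given the seed, different across seeds
  m2 <- initParams(eo$F, eo$S, eo$kernel, L = 1, gamma = 1, sigma2 = 0.1,
                   seed = 1)
  expect_identical(m@B, m2@B)
  expect_identical(m@X, m2@X)
  m3 <- initParams(eo$F, eo$S, eo$kernel, L = 1, gamma = 1, sigma2 = 0.1,
                   seed = 2)
  expect_false(identical(m@B, m3@B))
})

test_that("pseudo-EM objective is non-decreasing and the fit is reproducible", {
  sim <- simulateCilva(simulationConfig(N = 10L, T = 400L, L = 2L, seed = 5))
  ns <- estimateNoiseVariance(sim$F)
  fit <- fitCilva(sim$F, sim$S, L = 2, gamma = 0.4, sigma2 = ns$sigma2,
                  maxAlternations = 15, seed = 0, maxit = 60)
  obj <- objectiveTrace(fit)
  expect_true(all(diff(obj) >= -1e-6 * abs(obj[-length(obj)])))
  fit2 <- fitCilva(sim$F, sim$S, L = 2, gamma = 0.4, sigma2 = ns$sigma2,
                   maxAlternations = 15, seed = 0, maxit = 60)
  expect_identical(objectiveTrace(fit), objectiveTrace(fit2))
  expect_identical(factorActivity(fit), factorActivity(fit2))
})

test_that("an evoked-only fit (L = 0) matches the NNLS baseline regression", {
  sim <- simulateCilva(simulationConfig(N = 8L, T = 400L, xi = 0, pi = 0,
                                        sigma2 = 0.02, seed = 6))
  ns <- estimateNoiseVariance(sim$F)
  fit <- fitCilva(sim$F, sim$S, L = 0, gamma = 1, sigma2 = ns$sigma2,
                  maxAlternations = 30, seed = 0)
  Phi <- buildStimulusRegressors(sim$S, fittedModel(fit)@kernel)
  base <- nnlsEvoked(sim$F, Phi)
  fhat <- reconstruct(fittedModel(fit), sim$S)
  ## same quality of fit as the baseline on the same regressors
  expect_equal(meanRowCor(traces(sim$F), fhat),
               meanRowCor(traces(sim$F), base$evoked), tolerance = 1e-3)
})

test_that("standardisation preserves reconstructions and is idempotent", {
  inst <- randomInstance(N = 5, K = 3, L = 3, Tt = 60, seed = 21)
  m <- inst$model
  ref <- reconstruct(m, inst$S)
  ms <- standardizeModel(m, inst$S)
  expect_equal(reconstruct(ms, inst$S), ref, tolerance = 1e-10)
  ## unit factor norms and unit intensity norms
  nrm <- sqrt(rowSums(ms@X^2))
  expect_equal(nrm, rep(1, 3), tolerance = 1e-10)
  lam <- intensityMatrix(ms@W, inst$S, ms@B, ms@X)
  expect_equal(sqrt(rowSums(lam^2)), rep(1, 5), tolerance = 1e-10)
  ## idempotent
  mss <- standardizeModel(ms, inst$S)
  expect_equal(mss@X, ms@X, tolerance = 1e-10)
  expect_equal(mss@W, ms@W, tolerance = 1e-10)
  expect_equal(mss@alpha, ms@alpha, tolerance = 1e-10)
})

test_that("standardisation orders scrambled factors by activity norm", {
  inst <- randomInstance(N = 4, K = 2, L = 3, Tt = 50, seed = 22)
  m <- inst$model
  ## scramble scales so the activity norms are clearly unsorted
  X <- m@X * c(1, 10, 3)
  m2 <- CilvaModel(m@alpha, m@beta, m@W, m@B, X, m@sigma2, m@gamma, m@kernel)
  ms <- standardizeModel(m2, inst$S)
  ## output order must follow descending pre-normalisation activity norm;
  ## identify each output row with its source row by correlation
  origOf <- apply(ms@X, 1, function(r)
    which.max(abs(cor(r, t(m@X)))))
  wantOrder <- order(-sqrt(rowSums(X^2)))
  expect_identical(as.integer(origOf), as.integer(wantOrder))
  expect_warning(
    standardizeModel(CilvaModel(m@alpha, m@beta, m@W, m@B,
                                rbind(m@X[1:2, ], 0), m@sigma2, m@gamma,
                                m@kernel), inst$S),
    "zero-norm")
})

test_that("latent inference recovers factors at low noise and is a fixed point", {
  sim <- simulateCilva(simulationConfig(N = 20L, T = 500L, L = 2L,
                                        xi = 0.04, pi = 0, sigma2 = 0.01,
                                        seed = 30))
  X <- inferLatents(sim$F, sim$model, sim$S, gamma = 0.4, seed = 1)
  for (l in 1:2)
    expect_gt(cor(X[l, ], factorActivity(sim$model)[l, ]), 0.9)
  ## re-running from the solution stays at the solution
  X2 <- inferLatents(sim$F, sim$model, sim$S, gamma = 0.4, init = X)
  expect_gt(cor(as.vector(X), as.vector(X2)), 0.999)
  ## strong sparsity drives the latents to zero
  X0 <- inferLatents(sim$F, sim$model, sim$S, gamma = 1e-8, seed = 1)
  expect_lt(max(X0), 1e-4)
})

test_that("kernel time-constant derivatives match finite differences", {
  kd <- cilva:::kernelWithDerivs(2.2, 2.9, 40)
  h <- 1e-7
  fdR <- (cilva:::kernelWithDerivs(2.2 + h, 2.9, 40)$k -
            cilva:::kernelWithDerivs(2.2 - h, 2.9, 40)$k) / (2 * h)
  fdD <- (cilva:::kernelWithDerivs(2.2, 2.9 + h, 40)$k -
            cilva:::kernelWithDerivs(2.2, 2.9 - h, 40)$k) / (2 * h)
  expect_lt(max(abs(kd$dTauR - fdR) / pmax(abs(fdR), 1)), 1e-6)
  expect_lt(max(abs(kd$dDelta - fdD) / pmax(abs(fdD), 1)), 1e-6)
})

test_that("time constants are recovered from evoked-only data", {
  sim <- simulateCilva(simulationConfig(N = 20L, T = 1000L, xi = 0, pi = 0,
                                        sigma2 = 0.005, seed = 2))
  tc <- estimateTimeConstants(sim$F, sim$S, eta = 1)
  expect_lt(abs(tc$tauR - 5.68 / 2.1646) / (5.68 / 2.1646), 0.15)
  expect_lt(abs(tc$tauD - 11.5 / 2.1646) / (11.5 / 2.1646), 0.15)
  ## a heavy penalty shrinks tauR + delta
  tcBig <- estimateTimeConstants(sim$F, sim$S, eta = 5e3,
                                 maxAlternations = 4)
  expect_lt(tcBig$tauR + tcBig$delta, tc$tauR + tc$delta)
})
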