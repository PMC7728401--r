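test_that("decomposition components include the baseline and sum to the fit", {
  inst <- randomInstance(N = 4, K = 2, L = 2, Tt = 40, seed = 31)
  m <- inst$model
  dt <- decomposeTraces(m, inst$S, inst$F)
  fhat <- reconstruct(m, inst$S)
  expect_equal(dt$evoked + dt$spont - m@beta, fhat, tolerance = 1e-10)
  expect_equal(dt$residual, traces(inst$F) - fhat, tolerance = 1e-10)
  ## no couplings: the spontaneous trace is the bare baseline
  m0 <- CilvaModel(m@alpha, m@beta, m@W, 0 * m@B, m@X, m@sigma2, m@gamma,
                   m@kernel)
  dt0 <- decomposeTraces(m0, inst$S)
  expect_equal(dt0$spont, matrix(m@beta, 4, 40), tolerance = 1e-12)
})

test_that("simulator ground truth decomposes exactly in the degenerate case", {
  sim <- simulateCilva(simulationConfig(N = 6L, T = 300L, pi = 0,
                                        sigma2 = 0, seed = 32))
  dt <- decomposeTraces(sim$model, sim$S)
  expect_equal(dt$evoked, sim$fEvokedTrue, tolerance = 1e-10)
  expect_equal(dt$spont, sim$fSpontTrue, tolerance = 1e-10)
  expect_equal(dt$evoked + dt$spont, traces(sim$F), tolerance = 1e-8)
})

test_that("variance components satisfy the decomposition identity", {
  inst <- randomInstance(N = 5, K = 3, L = 2, Tt = 60, seed = 33)
  dt <- decomposeTraces(inst$model, inst$S)
  vc <- varianceComponents(dt$evoked, dt$spont)
  fhat <- dt$evoked + dt$spont - inst$model@beta
  vhat <- apply(fhat, 1, var)
  expect_equal(vc$varE + vc$varS + 2 * vc$covES, vhat, tolerance = 1e-10)
  ## against the textbook sample-moment oracle
  for (n in 1:5) {
    expect_equal(vc$varE[n], var(dt$evoked[n, ]), tolerance = 1e-12)
    expect_equal(vc$covES[n], cov(dt$evoked[n, ], dt$spont[n, ]),
                 tolerance = 1e-12)
  }
  ## identical components (up to constant): var[fhat] = 4 var_e
  vc2 <- varianceComponents(dt$evoked, dt$evoked + 0.7)
  expect_equal(vc2$varE + vc2$varS + 2 * vc2$covES, 4 * vc2$varE,
               tolerance = 1e-10)
})

test_that("drive ratio hits its endpoints and formula values", {
  expect_equal(driveRatio(3, 1), 0.5)
  expect_equal(driveRatio(c(2, 0, 1, 0), c(0, 2, 1, 0)),
               c(1, -1, 0, NA_real_))
  set.seed(34)
  ve <- rexp(20); vs <- rexp(20)
  d <- driveRatio(ve, vs)
  expect_true(all(d >= -1 & d <= 1))
  expect_true(all((d == 1) == (vs == 0)))
})

test_that("private variability bound behaves at the extremes", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 50, seed = 35)
  m <- inst$model
  fhat <- reconstruct(m, inst$S)
  Fexact <- FluorescenceSet(fhat, fs = 2)
  pv <- correctedVariancePrivate(Fexact, fhat, rep(0, 3) + 1e-15)
  expect_equal(pv$privateVar, rep(0, 3), tolerance = 1e-10)
  ## an unmodelled transient raises the bound by its variance contribution
  pert <- fhat
  pert[1, 10:14] <- pert[1, 10:14] + 2
  pv2 <- correctedVariancePrivate(FluorescenceSet(pert, fs = 2), fhat,
                                  rep(1e-15, 3))
  expect_equal(pv2$privateVar[1], var(pert[1, ]) - var(fhat[1, ]),
               tolerance = 1e-10)
  expect_equal(pv2$privateVar[2:3], c(0, 0), tolerance = 1e-10)
})

test_that("pure-noise neurons have near-zero private variability on average", {
  set.seed(36)
  reps <- 200
  pvs <- replicate(reps, {
    x <- rnorm(300, sd = sqrt(0.1))
    F1 <- FluorescenceSet(matrix(x, 1), fs = 2)
    correctedVariancePrivate(F1, matrix(0, 1, 300), 0.1)$privateVar
  })
  expect_lt(abs(mean(pvs)), 3 * sd(pvs) / sqrt(reps))
})

test_that("factor contribution index matches the literal formula", {
  inst <- randomInstance(N = 5, K = 2, L = 3, Tt = 60, seed = 37)
  m <- inst$model
  ci <- factorContributionIndex(inst$F, m, inst$S)
  ## literal recomputation
  Fm <- traces(inst$F)
  fhat <- reconstruct(m, inst$S)
  corF <- sapply(1:5, function(n) cor(Fm[n, ], fhat[n, ]))
  for (l in 1:3) {
    ml <- CilvaModel(m@alpha, m@beta, m@W, m@B[, -l, drop = FALSE],
                     m@X[-l, , drop = FALSE], m@sigma2, m@gamma, m@kernel)
    fl <- reconstruct(ml, inst$S)
    corl <- sapply(1:5, function(n) cor(Fm[n, ], fl[n, ]))
    expect_equal(ci[l], 1 - mean(corl / corF), tolerance = 1e-10)
  }
  ## a factor nobody couples to contributes nothing
  B0 <- m@B; B0[, 2] <- 0
  m0 <- CilvaModel(m@alpha, m@beta, m@W, B0, m@X, m@sigma2, m@gamma,
                   m@kernel)
  ci0 <- factorContributionIndex(inst$F, m0, inst$S)
  expect_equal(ci0[2], 0, tolerance = 1e-10)
  ## no factors, no indices
  mL0 <- CilvaModel(m@alpha, m@beta, m@W, matrix(0, 5, 0),
                    matrix(0, 0, 60), m@sigma2, m@gamma, m@kernel)
  expect_length(factorContributionIndex(inst$F, mL0, inst$S), 0)
})

test_that("cumulative factor deletion reaches the evoked-only reconstruction", {
  inst <- randomInstance(N = 4, K = 2, L = 3, Tt = 50, seed = 38)
  m <- inst$model
  mNone <- CilvaModel(m@alpha, m@beta, m@W, matrix(0, 4, 0),
                      matrix(0, 0, 50), m@sigma2, m@gamma, m@kernel)
  dtE <- decomposeTraces(m, inst$S)
  expect_equal(reconstruct(mNone, inst$S), dtE$evoked, tolerance = 1e-10)
})

test_that("averaging-based tuning uses the 4th-7th post-onset frames", {
  Tt <- 60
  design <- matrix(0, 2, Tt)
  design[1, c(10, 30)] <- 1
  design[2, 50] <- 1
  S <- StimulusDesign(design)
  tr <- matrix(0, 1, Tt)
  tr[1, 10 + 4:7] <- 1                       # indicator on the window
  tr[1, 30 + 4:7] <- c(0.2, 0.2, 0.2, 0.2)   # second presentation mean 0.2
  F <- FluorescenceSet(tr, fs = 2)
  tc <- averagedTuningCurve(F, S)
  expect_equal(tc[1, 1], (1 + 0.2) / 2)
  expect_equal(tc[1, 2], 0)
  ## onsets too near the end are dropped, empty columns flagged NA
  design2 <- matrix(0, 1, 20)
  design2[1, 18] <- 1
  expect_warning(
    expect_warning(tc2 <- averagedTuningCurve(
      FluorescenceSet(matrix(1, 1, 20), fs = 2),
      StimulusDesign(design2)), "dropped"),
    "zero usable")
  expect_true(is.na(tc2[1, 1]))
})

test_that("model tuning curves scale with alpha and the kernel peak", {
  inst <- randomInstance(N = 3, K = 4, L = 1, Tt = 30, seed = 39)
  m <- inst$model
  mt <- modelTuningCurve(m)
  kmax <- max(kernelValues(m@kernel))
  expect_equal(mt, kmax * m@alpha * m@W, tolerance = 1e-12)
  m2 <- CilvaModel(2 * m@alpha, m@beta, m@W, m@B, m@X, m@sigma2, m@gamma,
                   m@kernel)
  expect_equal(modelTuningCurve(m2), 2 * mt, tolerance = 1e-12)
  ## kernel peak for tauR=1, tauD=2 sits at the integer argmax t = 1
  k <- makeKernel(1, 2)
  expect_equal(max(kernelValues(k)), exp(-1 / 2) - exp(-1),
               tolerance = 1e-12)
})

test_that("cyclic shuffles preserve moments and are seed-reproducible", {
  set.seed(40)
  M <- matrix(rnorm(3 * 80), 3, 80)
  sn <- shuffleNull(M, function(m) c(rowMeans(m), apply(m, 1, var)),
                    nShuffles = 25, seed = 9)
  ref <- c(rowMeans(M), apply(M, 1, var))
  for (i in seq_len(nrow(sn$values)))
    expect_equal(sn$values[i, ], ref, tolerance = 1e-12)
  sn2 <- shuffleNull(M, function(m) c(rowMeans(m), apply(m, 1, var)),
                     nShuffles = 25, seed = 9)
  expect_identical(sn$values, sn2$values)
})

test_that("shuffle-null covariance band shrinks roughly as 1/sqrt(T)", {
  set.seed(41)
  q95 <- sapply(c(500, 2000), function(Tt) {
    a <- rnorm(Tt); b <- rnorm(Tt)
    sn <- shuffleNull(rbind(a, b),
                      function(m) abs(cov(m[1, ], m[2, ])),
                      nShuffles = 400, seed = 2)
    sn$q95
  })
  ratio <- q95[1] / q95[2]
  expect_gt(ratio, sqrt(2000 / 500) * 0.6)
  expect_lt(ratio, sqrt(2000 / 500) * 1.7)
})

test_that("factor cross-correlograms normalise and localise shifts", {
  set.seed(42)
  x <- rexp(300) * rbinom(300, 1, 0.1)
  s <- 7
  y <- c(rep(0, s), x[seq_len(300 - s)])        # x shifted right by s
  cc <- factorCrossCorrelogram(rbind(x, x, y), maxLag = 12)
  lags <- as.integer(dimnames(cc)[[3]])
  expect_equal(unname(cc[1, 2, lags == 0]), 1, tolerance = 1e-10)
  expect_equal(unname(cc[1, 1, lags == 0]), 1, tolerance = 1e-10)
  expect_equal(lags[which.max(cc[1, 3, ])], s)
  ## independent sparse factors stay inside the white-noise band
  set.seed(43)
  Xi <- matrix(rexp(2 * 2000) * rbinom(2 * 2000, 1, 0.05), 2, 2000)
  cci <- factorCrossCorrelogram(Xi, maxLag = 10)
  expect_lt(max(abs(cci[1, 2, ])), 3 * 2 / sqrt(2000))
})

test_that("the assembled decomposition object is coherent", {
  inst <- randomInstance(N = 4, K = 2, L = 2, Tt = 50, seed = 44)
  dec <- cilvaDecompose(inst$F, inst$model, inst$S)
  expect_s4_class(dec, "CilvaDecomposition")
  d <- driveRatios(dec)
  expect_true(all(d[is.finite(d)] >= -1 & d[is.finite(d)] <= 1))
  tab <- decompositionTable(dec)
  expect_identical(nrow(tab), 4L)
  expect_true(all(c("driveRatio", "privateVar") %in% names(tab)))
})
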