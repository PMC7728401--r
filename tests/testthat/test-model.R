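test_that("intensity matches the elementwise definition", {
  inst <- randomInstance(N = 4, K = 3, L = 2, Tt = 30, seed = 2)
  m <- inst$model
  lam <- intensityMatrix(m@W, inst$S, m@B, m@X)
  Sm <- designMatrix(inst$S)
  for (n in 1:4) for (t in c(1, 7, 30))
    expect_equal(lam[n, t],
                 sum(m@W[n, ] * Sm[, t]) + sum(m@B[n, ] * m@X[, t]),
                 tolerance = 1e-12)
  ## pure stimulus drive when couplings vanish
  lam0 <- intensityMatrix(m@W, inst$S, 0 * m@B, m@X)
  expect_equal(lam0, m@W %*% Sm, tolerance = 1e-12)
  ## single factor active at one frame picks out the coupling vector
  X1 <- matrix(0, 1, 30); X1[1, 9] <- 1
  lam1 <- intensityMatrix(0 * m@W, inst$S, m@B[, 1, drop = FALSE], X1)
  expect_equal(lam1[, 9], m@B[, 1], tolerance = 1e-12)
  expect_true(all(lam1[, -9] == 0))
})

test_that("reconstruction composes convolution, scaling and baseline", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 35, seed = 4)
  m <- inst$model
  lam <- intensityMatrix(m@W, inst$S, m@B, m@X)
  oneShot <- m@alpha * convOracle(kernelValues(m@kernel), lam) + m@beta
  expect_equal(reconstruct(m, inst$S), oneShot, tolerance = 1e-10)
  ## alpha = 0 leaves only the baseline
  m0 <- CilvaModel(0 * m@alpha, m@beta, m@W, m@B, m@X, m@sigma2, m@gamma,
                   m@kernel)
  expect_equal(reconstruct(m0, inst$S),
               matrix(m@beta, 3, 35), tolerance = 1e-12)
  ## reconstruction never dips below the baseline
  expect_true(all(reconstruct(m, inst$S) >= m@beta - 1e-12))
})

test_that("reconstruction is monotone in alpha where the drive is positive", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 35, seed = 5)
  m <- inst$model
  lam <- intensityMatrix(m@W, inst$S, m@B, m@X)
  drive <- convolveCausal(m@kernel, lam)
  a2 <- m@alpha; a2[2] <- a2[2] * 1.5
  m2 <- CilvaModel(a2, m@beta, m@W, m@B, m@X, m@sigma2, m@gamma, m@kernel)
  d <- reconstruct(m2, inst$S) - reconstruct(m, inst$S)
  expect_true(all(d[2, drive[2, ] > 0] > 0))
  expect_true(all(abs(d[-2, ]) < 1e-12))
})

test_that("log-joint agrees with a term-by-term transcription", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 25, seed = 6)
  m <- inst$model
  Fm <- traces(inst$F)
  E <- Fm - reconstruct(m, inst$S)
  ref <- 0
  for (n in 1:3) for (t in 1:25)
    ref <- ref - E[n, t]^2 / (2 * m@sigma2[n]) -
      0.5 * log(2 * pi * m@sigma2[n])
  for (l in 1:2) for (t in 1:25)
    ref <- ref - m@X[l, t] / m@gamma - log(m@gamma)
  expect_equal(logJoint(inst$F, m, inst$S), ref, tolerance = 1e-10)
})

test_that("log-joint closed form at zero residual and zero latents", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 25, seed = 8)
  m <- inst$model
  m0 <- CilvaModel(m@alpha, m@beta, m@W, m@B, matrix(0, 2, 25), m@sigma2,
                   m@gamma, m@kernel)
  Fexact <- FluorescenceSet(reconstruct(m0, inst$S), fs = 2)
  expect_equal(logJoint(Fexact, m0, inst$S),
               -(25 / 2) * sum(log(2 * pi * m0@sigma2)) -
                 2 * 25 * log(m0@gamma),
               tolerance = 1e-10)
})

test_that("log-joint is invariant to neuron and joint factor permutations", {
  inst <- randomInstance(N = 4, K = 2, L = 3, Tt = 30, seed = 9)
  m <- inst$model
  v0 <- logJoint(inst$F, m, inst$S)
  pn <- c(3, 1, 4, 2)
  mP <- CilvaModel(m@alpha[pn], m@beta[pn], m@W[pn, ], m@B[pn, ], m@X,
                   m@sigma2[pn], m@gamma, m@kernel)
  FP <- FluorescenceSet(traces(inst$F)[pn, ], fs = 2)
  expect_equal(logJoint(FP, mP, inst$S), v0, tolerance = 1e-10)
  pl <- c(2, 3, 1)
  mL <- CilvaModel(m@alpha, m@beta, m@W, m@B[, pl], m@X[pl, ], m@sigma2,
                   m@gamma, m@kernel)
  expect_equal(logJoint(inst$F, mL, inst$S), v0, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (seed in 1:10) {
    inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 30, seed = seed)
    m <- inst$model
    g <- cilvaGradients(inst$F, m, inst$S)
    set.seed(seed + 100)
    checks <- list(
      list(slot = "alpha", idx = sample(3, 2), g = g$alpha),
      list(slot = "beta", idx = sample(3, 2), g = g$beta),
      list(slot = "W", idx = sample(6, 2), g = g$W),
      list(slot = "B", idx = sample(6, 2), g = g$B),
      list(slot = "X", idx = sample(60, 4), g = g$X))
    for (ch in checks) for (i in ch$idx) {
      fd <- fdLogJoint(inst$F, m, inst$S, ch$slot, i)
      err <- abs(ch$g[i] - fd) / max(1, abs(fd))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("gradients vanish at a perfect fit except the prior pull on X", {
  inst <- randomInstance(N = 3, K = 2, L = 2, Tt = 30, seed = 11)
  m <- inst$model
  Fexact <- FluorescenceSet(reconstruct(m, inst$S), fs = 2)
  g <- cilvaGradients(Fexact, m, inst$S)
  expect_equal(max(abs(g$alpha)), 0, tolerance = 1e-9)
  expect_equal(max(abs(g$beta)), 0, tolerance = 1e-9)
  expect_equal(max(abs(g$W)), 0, tolerance = 1e-9)
  expect_equal(max(abs(g$B)), 0, tolerance = 1e-9)
  expect_equal(g$X, matrix(-1 / m@gamma, 2, 30), tolerance = 1e-9)
  ## the prior pull disappears as gamma grows
  mInf <- CilvaModel(m@alpha, m@beta, m@W, m@B, m@X, m@sigma2, 1e12,
                     m@kernel)
  gInf <- cilvaGradients(Fexact, mInf, inst$S)
  expect_equal(max(abs(gInf$X)), 0, tolerance = 1e-10)
})
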