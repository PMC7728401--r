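## Pseudo-EM fitting: alternating bounded L-BFGS-B maximisations of the
## penalised log-joint over latent factors X (theta fixed) and parameters
## theta = (alpha, beta, W, B) (X fixed), all under box constraints >= 0,
## using the analytic gradients. sigma2 is estimated once beforehand and held
## fixed throughout.

#' Initialise model parameters
#'
#' Stimulus filters are initialised by per-neuron non-negative least squares
#' of the trace onto the stimulus regressors (rows of \eqn{k * s_i});
#' alpha ~ Normal(1, 0.01) clipped at 0; beta = 0; couplings ~ Uniform(0,1);
#' factor activity ~ Uniform(0, 1/5). Deterministic given the seed.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param kernel a \linkS4class{CalciumKernel}
#' @param L number of latent factors (>= 0)
#' @param gamma exponential prior mean
#' @param sigma2 per-neuron noise variances (from
#'   [estimateNoiseVariance()])
#' @param seed integer seed
#' @return an initial \linkS4class{CilvaModel}
#' @export
initParams <- function(F, S, kernel, L, gamma, sigma2, seed = 1L) {
  Fm <- F@traces
  Sm <- S@design
  N <- nrow(Fm); Tt <- ncol(Fm); K <- nrow(Sm)
  Phi <- convRowsCore(kernel@values, Sm)
  keep <- rowSums(abs(Phi)) > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " all-zero stimulus regressor(s) from NNLS init")
  W <- matrix(0, N, K)
  if (any(keep)) {
    C <- t(Phi[keep, , drop = FALSE])        # T x K'
    for (n in seq_len(N))
      W[n, keep] <- pracma::lsqnonneg(C, Fm[n, ])$x
  }
  withSeed(seed, {
    alpha <- pmax(0, stats::rnorm(N, 1, 0.1))
    B <- matrix(stats::runif(N * L), N, L)
    X <- matrix(stats::runif(L * Tt, 0, 1 / 5), L, Tt)
  })
  CilvaModel(alpha = alpha, beta = rep(0, N), W = W, B = B, X = X,
             sigma2 = sigma2, gamma = gamma, kernel = kernel)
}

## One L-BFGS-B maximisation of the log-joint over X with theta fixed.
## Returns the updated L x T matrix. Fm, Sm bare matrices.
xStep <- function(Fm, Phi, conv, alpha, beta, W, B, X, invs, gamma,
                  maxit, pgtol) {
  L <- nrow(X); Tt <- ncol(Fm)
  if (L == 0) return(X)
  R0 <- Fm - alpha * (W %*% Phi) - beta
  Ct <- t(B * (alpha * invs))                # L x N
  cache <- new.env(parent = emptyenv())
  evalAt <- function(xv) {
    if (!is.null(cache$xv) && identical(cache$xv, xv)) return(invisible(NULL))
    Xm <- matrix(xv, L, Tt)
    E <- R0 - alpha * (B %*% conv$fwd(Xm))
    cache$xv <- xv
    cache$E <- E
    cache$f <- 0.5 * sum(E * (E * invs)) + sum(Xm) / gamma
    invisible(NULL)
  }
  fn <- function(xv) { evalAt(xv); cache$f }
  gr <- function(xv) {
    evalAt(xv)
    as.vector(-(conv$adj(Ct %*% cache$E)) + 1 / gamma)
  }
  opt <- stats::optim(as.vector(X), fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, pgtol = pgtol))
  matrix(pmax(opt$par, 0), L, Tt)   # guard float dust at the bound
}

## One L-BFGS-B maximisation over theta = (alpha, beta, W, B) with X fixed.
thetaStep <- function(Fm, Phi, Xc, alpha, beta, W, B, invs,
                      maxit, pgtol) {
  N <- nrow(Fm); K <- nrow(Phi); L <- nrow(Xc)
  unpack <- function(p) {
    list(alpha = p[seq_len(N)],
         beta = p[N + seq_len(N)],
         W = matrix(p[2 * N + seq_len(N * K)], N, K),
         B = if (L > 0) matrix(p[2 * N + N * K + seq_len(N * L)], N, L)
             else matrix(0, N, 0))
  }
  cache <- new.env(parent = emptyenv())
  evalAt <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(invisible(NULL))
    th <- unpack(p)
    Klam <- th$W %*% Phi
    if (L > 0) Klam <- Klam + th$B %*% Xc
    E <- Fm - th$alpha * Klam - th$beta
    cache$p <- p; cache$th <- th; cache$Klam <- Klam; cache$E <- E
    cache$f <- 0.5 * sum(E * (E * invs))
    invisible(NULL)
  }
  fn <- function(p) { evalAt(p); cache$f }
  gr <- function(p) {
    evalAt(p)
    G <- cache$E * invs
    aG <- cache$th$alpha * G
    c(-.rowSums(G * cache$Klam, N, ncol(Fm)),
      -.rowSums(G, N, ncol(Fm)),
      -as.vector(aG %*% t(Phi)),
      if (L > 0) -as.vector(aG %*% t(Xc)))
  }
  p0 <- c(alpha, beta, as.vector(W), if (L > 0) as.vector(B))
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, pgtol = pgtol))
  unpack(pmax(opt$par, 0))   # guard float dust at the bound
}

fitOnce <- function(Fm, Sm, kernel, L, gamma, sigma2, maxAlternations, tol,
                    seed, maxit, pgtol, init = NULL) {
  N <- nrow(Fm); Tt <- ncol(Fm)
  k <- kernel@values
  Phi <- convRowsCore(k, Sm)
  conv <- makeRowConvolver(k, Tt)
  model <- if (is.null(init))
    initParams(FluorescenceSet(Fm, fs = 1), StimulusDesign0(Sm), kernel,
               L, gamma, sigma2, seed) else init
  alpha <- model@alpha; beta <- model@beta
  W <- model@W; B <- model@B; X <- model@X
  invs <- 1 / sigma2
  constGauss <- -(Tt / 2) * sum(log(2 * pi * sigma2))
  constPrior <- if (L > 0) -L * Tt * log(gamma) else 0
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxAlternations)) {
    if (L > 0)
      X <- xStep(Fm, Phi, conv, alpha, beta, W, B, X, invs, gamma,
                 maxit, pgtol)
    Xc <- if (L > 0) conv$fwd(X) else matrix(0, 0, Tt)
    th <- thetaStep(Fm, Phi, Xc, alpha, beta, W, B, invs, maxit, pgtol)
    alpha <- th$alpha; beta <- th$beta; W <- th$W; B <- th$B
    Klam <- W %*% Phi
    if (L > 0) Klam <- Klam + B %*% Xc
    E <- Fm - alpha * Klam - beta
    obj <- -0.5 * sum(E * (E * invs)) + constGauss +
      (if (L > 0) -sum(X) / gamma + constPrior else 0)
    if (!is.finite(obj))
      stop("non-finite objective at alternation ", it,
           "; check inputs and noise variances")
    objective <- c(objective, obj)
    if (it > 1 &&
        abs(obj - objective[it - 1]) < tol * (abs(objective[it - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  model <- CilvaModel(alpha, beta, W, B, X, sigma2, gamma, kernel)
  list(model = model, objective = objective, converged = converged)
}

## internal: wrap a bare design matrix without the 1-of-K validity check
## (used when re-entering fitOnce with shifted designs)
StimulusDesign0 <- function(Sm) {
  new("StimulusDesign", design = Sm,
      stimLabels = paste0("s", seq_len(nrow(Sm))),
      shiftCount = if (nrow(Sm) > 0 && any(colSums(Sm) > 1)) 1L else 0L)
}

#' Fit the latent variable model by pseudo-EM
#'
#' Alternates bounded quasi-Newton (L-BFGS-B) maximisations of the penalised
#' log-joint: over the latent factor activity X with parameters fixed, then
#' over the parameters (alpha, beta, W, B) with X fixed, both under
#' non-negativity constraints, until the relative objective change falls
#' below `tol` or `maxAlternations` is reached. Noise variances are
#' estimated once (or supplied) and held fixed. The returned model is
#' standardised for identifiability (see [standardizeModel()]).
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param S a \linkS4class{StimulusDesign}
#' @param L number of latent factors; L = 0 fits an evoked-only model
#' @param gamma exponential prior mean (sparsity; smaller = sparser)
#' @param kernel a \linkS4class{CalciumKernel}; defaults to the GCaMP6s
#'   kernel at the recording's imaging rate
#' @param sigma2 optional per-neuron noise variances; estimated from the
#'   high-frequency spectrum when NULL
#' @param maxAlternations maximum pseudo-EM alternations (default 100)
#' @param tol relative objective-change convergence threshold
#' @param seed integer seed for the random initialisation
#' @param restarts number of random restarts; the restart with the best
#'   training objective is returned (restart i uses seed + i - 1)
#' @param maxit per-subproblem L-BFGS-B iteration cap
#' @param pgtol per-subproblem projected-gradient tolerance
#' @param init optional \linkS4class{CilvaModel} to start from (overrides
#'   `restarts`)
#' @return a \linkS4class{CilvaFit}
#' @export
fitCilva <- function(F, S, L, gamma, kernel = defaultKernel(imagingRate(F)),
                     sigma2 = NULL, maxAlternations = 100L, tol = 1e-6,
                     seed = 1L, restarts = 1L, maxit = 500L, pgtol = 1e-8,
                     init = NULL) {
  stopifnot2(L >= 0, "L must be >= 0")
  stopifnot2(gamma > 0, "gamma must be > 0")
  stopifnot2(maxAlternations >= 1, "maxAlternations must be >= 1")
  if (is.null(sigma2)) sigma2 <- estimateNoiseVariance(F)$sigma2
  sigma2 <- pmax(sigma2, 1e-8)                # guard degenerate flat traces
  Fm <- F@traces; Sm <- S@design
  runs <- if (is.null(init)) seq_len(restarts) else 1L
  best <- NULL
  for (i in runs) {
    r <- fitOnce(Fm, Sm, kernel, L, gamma, sigma2, maxAlternations, tol,
                 seed + i - 1L, maxit, pgtol, init = init)
    if (is.null(best) ||
        utils::tail(r$objective, 1) > utils::tail(best$objective, 1))
      best <- r
  }
  model <- standardizeModel(best$model, S)
  new("CilvaFit", model = model, objective = best$objective,
      converged = best$converged,
      config = list(L = L, gamma = gamma,
                    maxAlternations = maxAlternations, tol = tol,
                    seed = seed, restarts = length(runs)))
}

#' Standardise a fitted model for identifiability
#'
#' Three steps: (1) sort factors by descending Euclidean norm of their
#' activity (stable sort, coupling columns reordered identically); (2)
#' rescale each factor to unit norm, moving its norm into the coupling
#' column; (3) per neuron, rescale (alpha, w, b) by the norm of the
#' intensity vector so that every lambda_n has unit norm. The reconstruction
#' is preserved to float tolerance and the transform is idempotent.
#' Zero-norm factors are left unscaled, ordered last, with a warning.
#'
#' @param model a \linkS4class{CilvaModel}
#' @param S the \linkS4class{StimulusDesign} used in the fit
#' @return the standardised \linkS4class{CilvaModel}
#' @export
standardizeModel <- function(model, S) {
  B <- model@B; X <- model@X; W <- model@W
  alpha <- model@alpha; beta <- model@beta
  L <- nrow(X)
  if (L > 0) {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) warning("zero-norm factor(s) left unscaled, ordered last")
    ## stable sort on a rounded key: float dust must not reorder factors on
    ## a second application (idempotence); ties keep the original index
    ord <- order(-signif(nrm, 10), seq_len(L))
    X <- X[ord, , drop = FALSE]
    B <- B[, ord, drop = FALSE]
    nrm <- nrm[ord]
    pos <- nrm > 0
    X[pos, ] <- X[pos, , drop = FALSE] / nrm[pos]
    B[, pos] <- sweep(B[, pos, drop = FALSE], 2, nrm[pos], `*`)
  }
  lam <- intensityMatrix(W, S, B, X)
  lnrm <- sqrt(rowSums(lam^2))
  pos <- lnrm > 0
  alpha[pos] <- alpha[pos] * lnrm[pos]
  W[pos, ] <- W[pos, , drop = FALSE] / lnrm[pos]
  if (L > 0) B[pos, ] <- B[pos, , drop = FALSE] / lnrm[pos]
  CilvaModel(alpha, beta, W, B, X, model@sigma2, model@gamma, model@kernel)
}

#' Infer latent factor activity with parameters fixed
#'
#' Maximises the penalised log-joint over X only, holding theta at the
#' supplied model's values; used for held-out evaluation during model
#' selection and to re-infer training latents under selected
#' hyperparameters.
#'
#' @param F a \linkS4class{FluorescenceSet}
#' @param model a fitted \linkS4class{CilvaModel} supplying theta, the
#'   kernel and sigma2
#' @param S a \linkS4class{StimulusDesign} matching F's frames
#' @param gamma prior mean; defaults to the model's
#' @param seed seed for the small random start
#' @param maxit L-BFGS-B iteration cap
#' @param pgtol projected-gradient tolerance
#' @param init optional starting L x T matrix (overrides the random start)
#' @return the inferred L x T factor activity matrix
#' @export
inferLatents <- function(F, model, S, gamma = model@gamma, seed = 1L,
                         maxit = 500L, pgtol = 1e-8, init = NULL) {
  Fm <- F@traces; Sm <- S@design
  L <- ncol(model@B); Tt <- ncol(Fm)
  if (L == 0) return(matrix(0, 0, Tt))
  k <- model@kernel@values
  Phi <- convRowsCore(k, Sm)
  X0 <- if (is.null(init))
    withSeed(seed, matrix(stats::runif(L * Tt, 0, 1 / 5), L, Tt)) else init
  xStep(Fm, Phi, makeRowConvolver(k, Tt), model@alpha, model@beta,
        model@W, model@B, X0, 1 / model@sigma2, gamma, maxit, pgtol)
}
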