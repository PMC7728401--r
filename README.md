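# cilva

Decomposition of single-trial calcium imaging traces into stimulus-evoked
and low-dimensional spontaneous components.

## The problem

Calcium imaging of neural populations superimposes two signals in every
ΔF/F trace: responses evoked by the presented stimuli, and spontaneous
activity that is often coordinated across subsets of neurons. On single
trials the two are confounded — a spontaneous transient near a stimulus
onset inflates any tuning estimate based on averaging or regression. This
package is for experimenters and analysts who need the two components
separated trace by trace: per-neuron evoked and spontaneous time series,
variance budgets, tuning curves uncontaminated by spontaneous events, and
the latent factor time series that coordinate shared spontaneous activity.

## The model

Observed fluorescence is a scaled, kernel-convolved intensity plus
baseline and Gaussian noise:

    f_n(t) = alpha_n (k * lambda_n)(t) + beta_n + eps_n(t),
    eps_n(t) ~ N(0, sigma_n^2)

with the GCaMP impulse response `k(t) = exp(-t/tau_d) - exp(-t/tau_r)` and
a non-negative intensity combining the stimulus drive and L latent
factors:

    lambda_n(t) = w_n' s(t) + b_n' x(t)

`s(t)` is the binary 1-of-K stimulus vector, `w_n >= 0` the stimulus
filter, `b_n >= 0` the factor couplings, and `x(t) >= 0` the shared factor
activity, carrying an exponential sparsity prior with mean `gamma`.
Fitting is MAP inference by pseudo-EM: alternating box-constrained
L-BFGS-B maximisations of the penalised log-joint over `x` and over
`(alpha, beta, W, B)`, with analytic gradients, noise variances estimated
beforehand from the high-frequency power spectrum and held fixed, and a
standardisation step that makes the factorisation identifiable. A
two-stage NNLS + NMF baseline, a held-out hyperparameter-selection
routine, and a ground-truth simulator (zebrafish-like and mouse-like
regimes) are included. See the methods vignette
(`vignettes/cilva-methods.Rmd`) for assumptions, parameter meanings and
numerical choices.

## Worked example

Simulate a small zebrafish-like population with known ground truth, fit a
3-factor model, and decompose:

```r
library(cilva)

sim   <- simulateCilva(simulationConfig(N = 30L, T = 1200L, seed = 1))
sim$F
#> FluorescenceSet: 30 neurons x 1200 frames at 2.1646 Hz
sim$S
#> StimulusDesign: 9 stimuli x 1200 frames; 27 onsets

noise <- estimateNoiseVariance(sim$F)     # true sigma^2 is 0.1
round(head(noise$sigma2, 4), 3)
#> [1] 0.121 0.120 0.096 0.093

fit <- fitCilva(sim$F, sim$S, L = 3, gamma = 0.4, sigma2 = noise$sigma2,
                maxAlternations = 40, seed = 1, maxit = 100)
fit
#> CilvaFit: 40 alternations, not converged, final objective -36252.13
#> CilvaModel: 30 neurons, 9 stimuli, 3 factors, 1200 frames; gamma = 0.4

dec <- cilvaDecompose(sim$F, fit, sim$S)
round(contributionIndices(dec), 3)
#> [1] 0.151 0.131 0.116
head(decompositionTable(dec), 3)
#>   neuron  varEvoked   varSpont        covES driveRatio privateVar
#> 1      1 0.05878494 0.03421458  0.001941840  0.2641988 0.09071967
#> 2      2 0.49350740 0.73496812  0.042153010 -0.1965531 0.66538214
#> 3      3 0.02056360 0.04851698 -0.002921153 -0.4046490 0.05395543
```

The contribution indices say each factor accounts for roughly a 12–15%
drop in mean fit correlation if deleted; the per-neuron table gives each
neuron's evoked/spontaneous variance split, its drive ratio (+1 purely
evoked, −1 purely spontaneous), and an upper bound on private
variability. Because this is simulated data the recovery can be checked
against ground truth — here the mean correlation between true and
recovered evoked components is 0.91:

```r
mean(sapply(1:30, function(n)
  cor(sim$fEvokedTrue[n, ], evokedTraces(dec)[n, ])))
#> [1] 0.9110598
```

`selectHyperparams()` picks `gamma` on held-out data, `correlationVsL()`
guides the choice of L by its elbow, and `residualNmf()` runs the NNLS +
NMF comparison method. A thin command-line wrapper lives in
`inst/scripts/cilva.R` (subcommands `simulate | fit | decompose |
baseline`, driven by a YAML/JSON config).

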