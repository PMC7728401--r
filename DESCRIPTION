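Package: cilva
Title: Calcium Imaging Latent Variable Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes single-trial calcium imaging fluorescence traces into
    stimulus-evoked and low-dimensional shared spontaneous components under a
    generative model in which a difference-of-exponentials calcium kernel is
    convolved with a non-negative intensity comprising a stimulus drive and a
    sparse latent-factor drive. Model fitting is by MAP inference with an
    exponential sparsity prior on the latent factors, alternating bounded
    quasi-Newton maximisations over factors and parameters (pseudo-EM).
    Includes per-neuron imaging-noise estimation from the high-frequency power
    spectrum, hyperparameter selection on held-out data, variance
    decompositions and drive ratios, factor contribution indices, a two-stage
    NNLS + NMF baseline for comparison, and a synthetic-data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'kernel.R'
    'model.R'
    'noise.R'
    'inference.R'
    'timeconstants.R'
    'selection.R'
    'decomposition.R'
    'baseline.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
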