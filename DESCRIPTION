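Package: varsweep
Title: Property-Scale Ensemble Regression for Protein Variant Pre-Screening
Version: 0.1.0
Authors@R:
    person("Variant", "Sweep Maintainers", email = "maintainers@varsweep.dev",
           role = c("aut", "cre"))
Description: Toolkit for machine-learning-guided engineering of protein
    variant libraries, built around genetically encoded fluorescent
    indicators such as GCaMP. Parses mutation-list variant libraries against
    a base construct, encodes sequences with amino-acid property scales
    (AAINDEX-style indices), sweeps three regressor families (bagged
    regression trees, k-nearest neighbours, feedforward networks) over a
    property dictionary with univariate feature selection and grid search,
    stacks the best contributors into a mean ensemble, generates and
    pre-screens in-silico single-point saturation-mutagenesis libraries,
    analyses predictions (per-variant change from base, unpaired t-tests,
    sigma bands, residue prevalence in prediction extremes), clusters
    encodings via PCA and k-means with the elbow rule, and quantifies
    fluorescence time-series traces (dF/F0, SNR, exponential decay constant,
    half-decay time, dynamic range, SNR/tau performance score). Includes a
    synthetic genotype-phenotype simulator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    digest,
    withr,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    FNN,
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
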