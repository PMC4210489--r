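Package: divshift
Title: Episodic Birth-Death Diversification Analysis on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits episodic (piecewise-constant) birth-death models with rate
    shifts to the branching times of ultrametric chronograms under incomplete
    taxon sampling, performs grid search over shift times with sequential
    likelihood-ratio and AICc model selection, decomposes net diversification
    and turnover into speciation and extinction rates, back-projects standing
    diversity to an analysis horizon to derive sampling fractions via
    method-of-moments estimators, and reconstructs ancestral states of a
    binary habitat character under a one-parameter symmetric Markov model.
    Includes a forward birth-death tree simulator with rho-sampling for
    generating synthetic posterior chronogram samples, and an orchestration
    layer reproducing the full analysis chain with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
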