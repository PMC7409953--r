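Package: idpscore
Title: Bayesian Ensemble Scoring and Monte Carlo Selection for Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum log-likelihood scoring of intrinsically disordered protein
    conformer ensembles against heterogeneous solution data (chemical shifts,
    J-couplings, NOE and PRE distance restraints, residual dipolar couplings,
    hydrodynamic radius, smFRET transfer efficiency, SAXS intensities), with
    Gaussian nuisance parameters for back-calculation and experimental
    uncertainty optimized in closed form, Shannon-channel weighting of SAXS
    curves, and greedy or Metropolis Monte Carlo conformer-swap optimization
    of sub-ensembles with O(1)-per-swap incremental score updates. Includes a
    synthetic-fixture generator for ground-truth mixture pools.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
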