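Package: paleosweep
Title: Selection Trajectories, Conditional Wright-Fisher Simulation and
    Ancient-DNA Authentication for a Pre-Neolithic Sweep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether the near-fixation of a derived allele in
    Europe predates the Neolithic. Implements the deterministic single-locus
    viability-selection recursion with time-to-frequency solvers, a seeded
    forward Wright-Fisher simulator under a scaled three-population
    Out-of-Africa demographic timeline, rejection sampling conditional on
    present-day African allele frequency, the exact binomial lower bound on
    allele frequency from monomorphic ancient samples, and ancient-DNA
    authentication computations (post-mortem damage profiling from cloned PCR
    products, mtDNA HVR-I contamination screening, replicate concordance and
    qPCR standard-curve quantitation), together with seeded synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
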