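# paleosweep

Did Europe lose functional caspase-12 before the Neolithic? The derived T
allele at the *CASP12* nonsense polymorphism rs497116 — which truncates the
protein and lowers sepsis risk — is essentially fixed in Eurasia but still
polymorphic in sub-Saharan Africa (T at ~0.4 in hunter-gatherer populations,
~0.8 in farmers). If its rise in Europe was driven by zoonotic infections
that arrived with animal husbandry, the sweep should postdate the local
onset of the Neolithic. `paleosweep` implements the computational analyses
that test this dating, for population geneticists and ancient-DNA
practitioners:

* **Deterministic selection trajectories** — the single-locus recursion
  `p' = p(p·wAA + q·wAa)/w̄` with `w̄ = p²wAA + 2pq·wAa + q²waa`, under
  viability (`wAA = 1, wAa = 1−hs, waa = 1−s`), genic and additive
  parameterizations, with time-to-frequency solvers and the closed-form
  additive check `t ≈ (2/s)·ln(p₂q₁/p₁q₂)`.
* **Forward Wright–Fisher simulation** of a single locus under a scaled
  three-population Out-of-Africa demography (ancestral N₀ = 500 diploids,
  607 scaled generations, bottlenecks, growth and time-varying migration),
  with rejection sampling conditional on the present-day African frequency
  lying in [0.3, 0.5].
* **The monomorphic-sample frequency bound** — observing only the T allele
  in k independent copies bounds the true frequency below by `α^(1/k)`
  (exact one-sided binomial); 17 all-TT individuals at one Late-Neolithic
  site give p ≥ 0.838 at α = 0.05.
* **Ancient-DNA authentication** — post-mortem damage profiling of cloned
  PCR products, mtDNA HVR-I contamination screening against investigator
  haplotypes, replicate concordance, and qPCR standard-curve quantitation
  (`E = 10^(−1/slope) − 1`).
* **Seeded synthetic-data generators** for every input (genotype tables
  with allelic dropout, clone sets with per-type damage, haplotype surveys
  with planted contamination, dilution series), so the full pipeline is
  testable without any prehistoric specimen.

See the methods vignette (`vignettes/paleosweep-methods.Rmd`) for the
models, parameter conventions and design decisions.

## Worked example

```r
library(paleosweep)

## the exact lower bound from the best-represented ancient site
minCompatibleFrequency(17, 0.05)
#> FrequencyBound: p_min = 0.8384  (k = 17, alpha = 0.05)

## the packaged prehistoric genotype table
summarizeGenotypeTable(casp12AncientTable())$perSite
#>    Erralla  La Chora La Pasiega    Longar   Marizulo      SJAPL
#>          1         1          1         3          1         17

## neutral conditional experiment: P(EUR ≥ 0.95 today | AFR in [0.3, 0.5])
m <- ooaScaledModel()
estimateConditionalProbability(m, neutralScheme(), seed = 101,
                               nAcceptedTarget = 2000)
#> ConditionalEstimate
#>   accepted 2083 / 275000 raw replicates; successes 63
#>   p_hat = 0.0302  (95% CI 0.0233-0.0385)  seed 101

## how fast can the allele move deterministically at s = 1%, h = 0.11?
sweepTimeSensitivity(0.4, 0.8, s = 0.01, h = 0.11)
#>        parameterization generations
#> 1             viability    457.0000
#> 2                 genic    181.0000
#> 3              additive    357.0000
#> 4  additive_closed_form    358.3519
```

Reading the output: the frequency bound says the data are incompatible
(at α = 0.05) with a T frequency below 0.838 at ~5,000 years before
present, i.e. the European sweep was essentially complete before animal
husbandry matured locally. The conditional estimate says that under
neutrality only ~3% of demographically consistent histories reach the
observed European near-fixation — rejecting neutral evolution — and the
companion experiment with additive selection since the allele's origin
gives a similarly small probability (~2%), rejecting uniform
selection-since-origin as well. The sensitivity table quantifies a
documented tension: the literal viability recursion at the nominal (s, h)
needs ~457 generations for the 0.4 → 0.8 transit, not the ~200 sometimes
quoted; only the genic variant approaches the shorter figure.

`runFullAnalysis(seed = 1)` sequences all stages (recursion sensitivity,
both conditional experiments, the 7,000-years-before-present record-point
summary, frequency bound, genotype summary, QC parameter recovery) and
`renderReport()` prints them next to the package's benchmark values.

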