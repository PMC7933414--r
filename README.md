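# RootRD

Tooth-root morphology varies between people — one to four separate roots, or
an unseparated C-shaped root — and part of that variation tracks the *EDAR*
370V/A polymorphism (rs3827760) common in East Asian populations. RootRD is
an R package for studying this system from both ends:

* **Morphodynamic simulation.** An activator–inhibitor reaction–diffusion
  system runs on a growing two-dimensional polygonal cell network (a vertex
  model: wall elasticity `kS(l − l0)` plus turgor pressure `kP/V`, overdamped
  vertex dynamics). The tissue grows from 10 to 1000 cells by repeated cycles
  of largest-cell division → mechanical relaxation → reaction–diffusion
  (per-cell dynamics `du/dt = φ(ε + αs·u − β·v) − (αd + ψ)·u + Du·Σ(uj − ui)`,
  `dv/dt = γ·u − δ·v + Dv·Σ(vj − vi)`, with a synthesis clamp `φ` and extra
  marginal-cell decay `ψ = αm`). A classifier maps the final activator field
  to a root-type label (1–4 compact regions, an arc-like "C", or "other").
* **Association statistics.** Exact r×c contingency tests (Freeman–Halton
  enumeration), covariate-adjusted logistic regression with Wald χ², and
  Spearman rank correlations with tied ranks — including a closed-form
  version computed directly from contingency-table counts — plus a synthetic
  cohort generator that emulates the reference study design (genotype
  frequencies, covariate distributions, published effect sizes) so the whole
  battery runs without patient data.

Intended users: developmental/systems biologists experimenting with
patterning mechanisms on cell networks, and dental anthropologists or
statistical geneticists who want the exact analysis pipeline for ordinal
genotype–trait tables.

## Worked example

```r
library(RootRD)

# published genotype-by-root-class counts, five tooth types
counts <- edarRootCounts()
round(sapply(counts, function(tab) fisherExactRxC(tab)$p), 5)
#>     UP1     UP2     UM2     LM1     LM2
#> 0.01045 0.90973 0.46965 0.11677 0.00087
round(sapply(counts, function(tab) spearmanFromTable(tab)$rho), 4)
#>     UP1     UP2     UM2     LM1     LM2
#> -0.1855 -0.0235 -0.0061  0.1351 -0.2416
```

The exact P values say the genotype is associated with the root form of the
first upper premolar (P = 0.010) and the second lower molar (P = 0.00087)
but not the other teeth; the correlations give the direction — the A allele
goes with *fewer* UP1 roots (negative ρ against the ordering [1, 2≤]), *more*
LM1 roots, and the C-shaped LM2 root. (Four of the five published ρ values
reproduce exactly from the published counts; for LM2 the counts give
−0.2416 where −0.2327 was published — see the methods vignette.)

```r
# a synthetic cohort with the published design and effect sizes
cohort <- generateCohort(cohortModel(n = 5000), seed = 42)
fit <- rootTraitLogistic(cohort, "LM2")
subset(fit$coefficients, term == "genotype")
#>       term     logOR        se    chisq            p
#> 5 genotype 0.8540872 0.0488891 305.1971 2.429579e-68
```

The generator plants a genotype log odds ratio of 0.858 on the C-shaped LM2
root; the fit recovers it (0.854 ± 0.049) with the Wald machinery used for
the published table.

```r
# grow a tissue and classify the final activator field
cfg <- simulationConfig(rd = rdParams(alphaS = 1.8, gamma = 1.0),
                        nStart = 10, nEnd = 250, seed = 3)
res <- runSimulation(cfg)
classifyPattern(res$network, res$state, cfg@rd)
#> PatternSummary: reverse_spotted, 1 region(s), root label C
#>   areaFraction circularity angularExtent
#> 1        0.336       0.059         6.115
```

At the reference constants the spatial structure is a boundary rim driven by
the marginal-decay term (here a C-like annulus of suppressed activator);
interior spot multiplicity needs a higher inhibitor/activator diffusion
ratio — the methods vignette derives the stability boundary and shows how to
cross it (`rdParams(Du = 0.05, Dv = 2)`).

A command-line interface wraps the same functions
(`inst/scripts/rootrd simulate|classify|associate|synth`); networks travel
as JSON, states and cohorts as CSV, snapshots as SVG.

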