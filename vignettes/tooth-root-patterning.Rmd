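---
title: "Modelling tooth-root patterning and dental trait association with RootRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tooth-root patterning and dental trait association with RootRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RootRD)
```

## The problem

The number and shape of human tooth roots (one to four separate roots, or an
unseparated C-shaped root) vary between individuals and populations, and part
of that variation tracks the *EDAR* 370V/A polymorphism, whose derived A
allele is common in East Asian populations. RootRD packages two connected
toolsets around this problem:

1. a **morphodynamic simulation** of the apical surface of the dental papilla
   at the onset of root formation — an activator–inhibitor reaction–diffusion
   (RD) system running on a growing, mechanically relaxed polygonal cell
   network — together with a classifier that maps the final activator field
   to a root-type label;
2. the **association statistics** used for dental traits: exact r×c
   contingency tests (Freeman–Halton), covariate-adjusted logistic regression
   with Wald tests, and Spearman rank correlations with tied ranks, plus a
   synthetic cohort generator emulating the reference study design so the
   whole battery is testable without patient data.

## The cell-network (vertex) model

Cells are simple polygons tiling a 2-D domain, separated by straight walls
and sharing vertices. Vertex $i$ at position $\mathbf{u}_i$ moves by
overdamped dynamics $d\mathbf{u}_i/dt = k_T \mathbf{F}_i$, where
$\mathbf{F}_i$ sums, over the walls $j$ meeting the vertex:

* a **wall elasticity** of magnitude $k_S\,(l_j - l_0)$ along the wall axis,
  restoring the wall length $l_j$ toward the rest length $l_0$; and
* **turgor pressure** from each adjacent cell $m$, of magnitude
  $k_P / V_{jm}$ (inverse to the cell area $V_{jm}$), perpendicular to the
  wall and outward from the pressing cell, applied equally to both endpoint
  vertices. Boundary walls feel only their single cell.

Constants default to $k_T = 0.5$, $k_S = 1.0$, $l_0 = 0.3$, $k_P = 1.0$
(dimensionless units). At regular intervals the **largest cell divides** by a
new straight wall through its area centroid at a uniformly random angle; a
line that grazes an existing vertex, or that does not cross exactly two
walls, is redrawn (bounded retries). Daughter areas sum exactly to the
mother's area before relaxation, and the two new vertices are inserted into
the neighbouring cells' polygons so the tiling stays conforming.

**Numerical choices.** Relaxation integrates the vertex dynamics by explicit
Euler with step 0.2 until the largest per-step displacement falls below
4×10⁻⁴ (an exit force threshold $|k_T\mathbf{F}| < 2\times10^{-3}$,
independent of the step), capped at 10⁴ iterations. The step sits well
inside the stability limit of the stiffest mode (~$2/(k_Tk_S)$); we chose it
after observing that a 4× smaller step only slowed convergence without
changing the relaxed geometry. After each division the local misfit
relaxes in a few hundred iterations; the residual non-converged mode, when
the cap is hit, is the slow global inflation of the tissue (diffusive in
the cell number), which does not affect the RD pattern. Growth sweeps use a
per-cycle budget of 2000 iterations. If a near-degenerate cell (a thin
Voronoi sliver) turns inside out at the standard step, the relaxation
restarts deterministically from the original positions at a 5× (then 25×)
smaller step. Ties for the largest cell break to the smallest cell id, so
runs are fully reproducible.

**Initial condition.** The starting tissue is a Voronoi partition of
`nStart` uniformly sampled points (with a minimum-separation rejection rule)
in a disk approximated by a regular 24-gon, built by half-plane clipping and
then relaxed. All randomness — initial geometry, initial fluctuation,
division angles and redraws — comes from one stream seeded once per run.

## The reaction–diffusion model

Each cell $i$ carries an activator $u_i$ and an inhibitor $v_i$:

$$\frac{du_i}{dt} = \varphi(\varepsilon + \alpha_s u_i - \beta v_i)
  - (\alpha_d + \psi_i)\,u_i + D_u \sum_{j \in N(i)} (u_j - u_i)$$
$$\frac{dv_i}{dt} = \gamma u_i - \delta v_i
  + D_v \sum_{j \in N(i)} (v_j - v_i)$$

with $\varphi$ clamping synthesis to $[0, \alpha_d u_{max}]$ and $\psi_i =
\alpha_m$ in marginal (boundary) cells, 0 otherwise. The diffusion sum runs
unweighted over wall-sharing neighbours. The homogeneous equilibrium of
non-marginal cells is $u_0 = \delta\varepsilon/(\beta\gamma -
(\alpha_s-\alpha_d)\delta)$, $v_0 = \gamma\varepsilon/(\beta\gamma -
(\alpha_s-\alpha_d)\delta)$, defined when the denominator is positive.
$\alpha_s$ and $\gamma$ are the strengths of activator and inhibitor
synthesis — the two knobs a hyperfunctional EDAR variant is hypothesised to
turn together. The saturation $u_{max}$ is set as a multiple of $u_0$: 10
("high" regime) or 1.1 ("low" regime), paired with $\alpha_m = 1$ and
$-0.1$ respectively; the remaining defaults are $\alpha_d = \beta = \delta =
\varepsilon = 1$, $D_u = 0.25$, $D_v = 0.5$.

Each growth cycle runs exactly $T_d/dt = 50/0.02 = 2500$ Euler steps (a
fixed count, not a convergence test — the dynamics are near-steady well
within one cycle), after which the largest cell divides, daughters
inheriting the mother's concentrations unchanged. After every step $u$ is
clipped to $[0, u_{max}]$ (the stated bound, enforced against Euler
overshoot) and $v$ to $[0, \infty)$ — the inhibitor is nowhere stated to be
bounded above, so only non-negativity is imposed. Runs start from the
equilibrium with a uniform ±1% fluctuation.

### What the default constants can and cannot do

A point that matters for interpreting simulation output: at the default
constants the interior linearization has $f_u = \alpha_s - \alpha_d$,
$f_v = -\beta$, $g_u = \gamma$, $g_v = -\delta$, and the dispersion
relation

$$\det(\mu) = D_uD_v\mu^2 - (f_uD_v + g_vD_u)\,\mu + (f_ug_v - f_vg_u)$$

is positive for every $\mu \ge 0$ (at $\alpha_s = 1.8$, $\gamma = 1$:
$0.125\mu^2 - 0.15\mu + 0.2$, minimum 0.155). A diffusion-driven (Turing)
instability of the homogeneous state requires $D_v/D_u \gtrsim 3.2$ at
$\alpha_s = 1.8$, and more at lower $\alpha_s$; the default ratio is 2. Nor
does a saturated high state coexist with $u_0$ (self-consistency of the
$\varphi$ ceiling would require $u_{max} \le \varepsilon/(\alpha_d +
\beta\gamma/\delta - \alpha_s)$, which is below $u_0$). Consequently, with
the default coefficients the interior field homogenizes — we verified this
both on the growing network and on an independent fixed-lattice
reimplementation, from small and from large-amplitude random initial fields
— and the spatial structure that *does* form is driven by the
marginal-decay term: a boundary rim of suppressed (high regime) or elevated
(low regime) activator, as the $\psi$ term is designed to produce. Users
who want interior spot patterns (discrete activator maxima away from the
rim) should raise the inhibitor/activator diffusion ratio, e.g. `rdParams(Du
= 0.05, Dv = 2)`; the linear-stability test in the suite demonstrates the
onset against an eigenvalue oracle. The package deliberately keeps the
reference constants as defaults rather than silently substituting
pattern-forming ones.

## Pattern classification

`classifyPattern()` operationalizes a visual taxonomy explicitly: cells are
labelled HIGH above the midrange $(\min u + \max u)/2$ (invariant under
affine rescaling of $u$); a range below 5% of $u_0$ is declared homogeneous.
The **minority phase by area** defines the figure: polarity is *spotted*
when the minority is HIGH, *reverse-spotted* when LOW (an exact 50/50 split
breaks to HIGH). Connected components of minority cells over the
wall-sharing graph are the regions; each gets an area fraction, perimeter,
circularity $4\pi A/P^2$ and angular extent around the tissue centroid. The
label is the region count ("1"–"4") when 1–4 regions are all compact
(circularity ≥ 0.4); a single elongated region (circularity < 0.4) spanning
≥ 120° is "C"; anything else is "other". The 0.4 and 120° thresholds are
fixed, documented choices: painted-field tests (k compact disks, k = 1..4,
and an arc painted directly onto a real grown network) recover the intended
label in ≥ 95% of trials, which is what those thresholds were chosen to
achieve on synthetic fields — they carry no claim of matching any visual
scoring of real simulations.

## Association statistics

Phenotypes are coded per tooth and side (`1, 2, 3, 4` roots, `C` C-shaped,
`m` congenitally missing; `absent` = lost to extraction/treatment, which
drops the individual from that tooth's analysis). `dichotomizeRoot()`
implements the published two-class side-combination groupings verbatim
(e.g. UP1 `1|1` vs `1|2, 2|2, 2|3`; LM2 `2|C, C|C` vs `2|2`); discordant
pairs belong to the group listing them, which encodes the
"less-common side phenotype" rule, and unlisted combinations are missing.

`fisherExactRxC()` is the Freeman–Halton generalization of Fisher's exact
test: all tables with the observed margins are enumerated recursively and
the two-sided P is the sum of hypergeometric probabilities of tables no
more probable than the observed one (tie tolerance 10⁻¹² on the log scale).
For the 3×2 tables this package targets, enumeration is a few thousand
tables; the suite cross-checks against the closed-form 2×2 hypergeometric
ordering and against an independent network-algorithm implementation.

`logisticFit()` delegates the maximum-likelihood fit to binomial IRLS
(`stats::glm`) and adds the Wald machinery ($\chi^2 = (\hat\beta/SE)^2$, P
from $\chi^2_1$) and a separation guard (any $|\hat\beta| > 15$ flags the
fit). Genotype enters as A-allele dosage (VV = 0, VA = 1, AA = 2), sex as
male = 0 / female = 1, region as the number of grandparents from the Ryukyu
Islands (0–4). We follow the published coefficient table's sex coding
rather than the alternative male = 1 / female = 2 coding mentioned
elsewhere in the source; the two differ only in the intercept.

`spearmanRank()` is Pearson correlation of mid-ranks; P uses the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (the source does not
state its method, so P values are reported but correlations are the
comparable quantity). `spearmanFromTable()` computes the identical
statistic in closed form from a contingency table's counts via mid-ranks of
the margins — the suite verifies it equals expansion-then-rank exactly.

Four of the five published genotype-vs-root correlations reproduce to four
decimals from the published counts (UP1 −0.1855, UP2 −0.0235, UM2 −0.0061,
LM1 0.1351). The published LM2 value (−0.2327) does not: the published
dichotomized LM2 counts give −0.2416, which is what this package computes
and asserts as the correct value from those counts. A finer 3-level
ordering of the discordant C-shaped sides can reproduce −0.2327, but the
required split is not published. The published genotype counts (25/120/112)
likewise sum to 257 against a stated cohort of 255; they are reported
verbatim and normalized where probabilities are needed.

## The synthetic cohort generator

`generateCohort()` draws genotypes multinomially at the published
frequencies, ages uniform on 20–69 years, sex at the published 157/255
female fraction, and region uniform on 0–4 (only totals/ranges are
published for these). Each tooth's dichotomized class follows a logistic
model whose genotype/age/sex/region log odds ratios default to the
published covariate-adjusted estimates (UP1 0.666, LM1 0.529, LM2 0.858 for
genotype; zero for the teeth with no published effect), with the intercept
centred so the marginal test-class prevalence matches the observed class
proportions under the model's covariate distribution. Side codes are then
synthesized consistently with the class; discordant left/right pairs appear
at a configurable 5% (the observed frequency of mixed two/three-rooted
first lower molars), exercising the less-common-side rule. Crown-trait
grades are generated with a strong genotype effect on incisor shoveling and
weak or no genotype effects elsewhere.

What the generator does *not* emulate: linkage or population structure,
family relatedness, covariate–phenotype dependencies beyond the published
estimates, inter-tooth phenotype correlations (each tooth is drawn
independently given covariates), or realistic missingness patterns. Tests
passing on synthetic cohorts therefore validate the statistical machinery
and its power under the published effect sizes — not any new biological
claim about real cohorts.

## Problem sizes used by the test suite

The suite runs everything at sizes chosen to keep a full check under half
an hour on one core while preserving the qualitative behaviour: growth
sweeps for polarity use 10 replicates per condition to 250 cells; the mean
region-count trends over $\alpha_s \in \{1.5..1.8\}$ and $\gamma \in
\{1.0..1.6\}$ use 20 replicates to 100 cells; parameter-recovery and power
checks use synthetic cohorts of 1 000–5 000; one full-scale growth run
(10 → 1000 cells, 990 cycles) verifies the growth bookkeeping end to end.
The acceptance script repeats that full-scale run from scratch at a
caller-supplied seed.

## Known limitations

* The tissue model has no T1 rearrangements, cell death, migration, or 3-D
  geometry (no epithelial invagination); growth is purely by division and
  pressure-driven expansion.
* "Equilibrium" in the mechanics is quasi-static under an iteration budget;
  the slow global inflation mode may still be relaxing when a cycle ends.
* At the default diffusion coefficients the RD interior is linearly stable,
  so root-type multiplicity (2–4 separate regions) is not produced by the
  defaults; see the stability discussion above.
* Exact-test enumeration is exponential in table size; intended for small
  r×c tables (the 3×2 tables here, or anything up to ~10⁵ candidate
  tables).
* Spearman P values use the large-sample t-approximation, not an exact
  permutation distribution.

## A minimal session

```{r example, eval = FALSE}
# grow a tissue and classify its final activator field
cfg <- simulationConfig(rd = rdParams(alphaS = 1.8, gamma = 1.0),
                        nStart = 10, nEnd = 250, seed = 1)
res <- runSimulation(cfg)
classifyPattern(res$network, res$state, cfg@rd)

# reproduce the published exact tests and correlations from the counts
sapply(edarRootCounts(), function(tab) fisherExactRxC(tab)$p)
sapply(edarRootCounts(), function(tab) spearmanFromTable(tab)$rho)

# synthetic cohort -> full association battery
cohort <- generateCohort(cohortModel(n = 255), seed = 7)
associationSummary(cohort)$fisher
```
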