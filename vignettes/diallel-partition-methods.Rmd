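---
title: "Partitioned combining-ability analysis of full diallels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned combining-ability analysis of full diallels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelpart)
```

## The estimation problem

A full (Method 1) diallel grows all p² ordered combinations of p inbred
parents — selfs, straight crosses and reciprocals — in r complete
blocks. The classical Griffing Model I analysis summarizes the p × p
table of entry means `x_ij` (female in rows) by one general combining
ability (GCA) per parent, one specific combining ability (SCA) per
unordered cross and one reciprocal effect per pair:

* `ĝ_i = (x_i. + x_.i)/(2p) − x_../p²`
* `ŝ_ij = (x_ij + x_ji)/2 − (x_i. + x_.i + x_j. + x_.j)/(2p) + x_../p²`
* `r̂_ij = (x_ij − x_ji)/2`

with `x_i.`, `x_.i`, `x_..` the row, column and grand totals of the
entry means. These are orthogonal projections of the table, so
`µ̂ + ĝ_i + ĝ_j + ŝ_ij + r̂_ij` reconstructs every cell exactly and the
usual zero-sum constraints hold; both facts are enforced as property
tests on random tables.

Griffing's `ĝ_i` deliberately averages a parent's marginal behaviour as
female and as male. When cytoplasmic inheritance or other maternal
pathways matter, the two roles differ and the average misleads. The
partition implemented here keeps them apart:

* `ĝ_fi = x_i./p − x_../p²` (parent used as female),
* `ĝ_mi = x_.i/p − x_../p²` (parent used as male),
* `ĝ_i = (ĝ_fi + ĝ_mi)/2` and the maternal effect
  `m̂_i = (ĝ_fi − ĝ_mi)/2`, identically equal to the marginal contrast
  `(x_i. − x_.i)/(2p)` — both closed forms are implemented and their
  equality is asserted to machine precision,
* a directional adjusted SCA
  `ŝ_ij = x_ij − (x_i. + x_.i + x_j. + x_.j)/(2p) + x_../p²`, whose
  pairwise average returns Griffing's SCA and whose half-difference
  `r_ij = (ŝ_ij − ŝ_ji)/2 = (x_ij − x_ji)/2` is the reciprocal effect.

One algebraic point is worth writing down because it is easy to get
wrong. The adjusted SCA subtracts *both* margins of each parent, so it
absorbs the entire directional deviation of a cell, maternal part
included: in the noiseless limit its estimand is
`s_ij + nm_ij + (m_i − m_j)`, where `s` is the symmetric SCA and `nm`
the non-maternal reciprocal deviation. Consequently the cell-wise
reconstruction identity that holds is

`x_ij = µ̂ + ĝ_i + ĝ_j + ŝ_ij(adjusted)`

with Griffing's *symmetric* GCA — not with `ĝ_fi + ĝ_mj`, whose sum
with the adjusted SCA over-counts the maternal difference once. The
test suite asserts the identity in the form that is true. Equivalently,
adjusted SCA = Griffing SCA + Griffing reciprocal effect.

The printed source for the adjusted-SCA closed form carries a bare 1/2
on the marginal-total term; only 1/(2p) makes the pair average equal
Griffing's SCA (and makes the expression dimensionally consistent when
written with totals), so 1/(2p) is what is implemented.

## ANOVA and tests

The plot data are decomposed as an RCBD (blocks = replications:
r − 1, p² − 1 and (p² − 1)(r − 1) df). Among entry means, the treatment
SS splits orthogonally into

* GCA (p − 1 df), SCA (p(p+1)/2 − p df), reciprocal (p(p−1)/2 df),
* reciprocal further into maternal `SS_M = Σ(x_i. − x_.i)²/(2p)`
  (p − 1 df; the quadratic form of the maternal estimator, and an
  orthogonal projection of the antisymmetric part, so `SS_M ≤ SS_Rec`
  always) and a non-maternal remainder.

SS and df additivity are property-tested against brute-force sums on
random instances. Every mean square is F-tested against the single
Model I error term `MS_resid/r`; under a pure-noise null the maternal
statistic is exactly F(p−1, (p²−1)(r−1))-distributed, and the suite
checks the empirical size at α = 0.05 over 1,000 null simulations
(accepting 0.03–0.07, the exact binomial band). Both entry-mean and
plot bases (×r) are reported for every line, since published tables are
frequently ambiguous about the basis.

Standard errors are not transcribed from printed formulas: each effect
is a fixed linear functional of the p² independent entry means (variance
`MS_resid/r` each), so the package builds the coefficient pattern of
each class and takes `SE = sqrt(var_mean · ‖c‖²)`. This reproduces the
Method 1 variance formulas by construction and is verified against a
10,000-draw Monte-Carlo of error-only diallels (3% tolerance).
Significance stars use two-sided normal-deviate tests at 0.05/0.01 with
no multiplicity correction, matching the annotation convention of
published diallel tables.

## Variance components and derived parameters

On the entry-mean basis the method-of-moments solution is

* `σ̂²e = MS_resid/r`
* `σ̂²gca = (MS_GCA − σ̂²e)/(2p)`
* `σ̂²sca = MS_SCA − σ̂²e`
* `σ̂²rca = (MS_Rec − σ̂²e)/2 ≡ (MS_Rec^plot − MS_resid^plot)/(2r)`

with negative estimates truncated to zero and flagged. Under fixed
(Model I) truth each mean square has expectation `MS_noiseless + σ²e`,
so defining the estimands as the corresponding quadratic forms of the
noiseless table makes these estimators exactly unbiased; the recovery
suite verifies mean estimates within 5% of truth over 2,000 simulated
trials of the default scenario.

Derived parameters use `σ²A = 2σ²gca`, `σ²D = σ²sca` and the phenotypic
composition `σ²P = σ²A + σ²D + σ²rca + σ²e/r`. The composition including
the reciprocal component and the per-entry error share is adopted as the
package's definition because it is the unique simple composition that
closes the full published 8-trait parameter table we validate against
(all eight σ²P values). Heritabilities are percentages,
`H² = 100(σ²A+σ²D)/σ²P` and `h² = 100σ²A/σ²P`; Baker's ratio is
`2σ²gca/(2σ²gca+σ²sca)` (0 when no genetic variance, in which case
heritabilities are 0 and, with σ²P = 0, reported missing).

Because published components are rounded (mostly to 2 decimals, one
value each to 1 and 3), cell-level closure of derived values is checked
by interval arithmetic: each printed input is treated as ±half a unit in
its last digit, the formulas are monotone in every component so corner
evaluation bounds the attainable range exactly, and the printed derived
value must fall in that range widened by half a unit of its own last
digit. The handful of point checks whose inputs are large enough for
rounding not to matter (H² for a low-error trait, h² and Baker's ratio
for yield) are asserted strictly at one unit in the last printed
decimal. Which expected-mean-square convention produced the published
GCA/SCA *components* from their published mean squares could not be
reconciled under any standard Method 1 EMS; those two estimators are
therefore validated by simulation recovery, not by table reproduction
(the reciprocal estimator does reconcile and is additionally checked
against the published kernel-row value).

## Heterosis and correlations

Mid-parent heterosis is `100(x_ij − MP)/MP` with `MP = (x_ii+x_jj)/2`;
better-parent heterosis uses the parent favoured by the trait's
direction (`max` for yield-type traits, `min` for phenology such as
days to tasseling/silking; configurable per trait). Crosses with a zero
MP or BP are flagged undefined rather than divided through.

Correlations between performance (F1 mean, MPH, BPH) and predictors
(Griffing SCA, adjusted SCA, Griffing SGCA `g_i+g_j`, adjusted SGCA
`g_fi+g_mj`) are Pearson coefficients over the p(p−1) ordered hybrids —
straight and reciprocal kept separate, since only then does the
adjusted SCA's directional information enter; a straight-only option
exists. The adjusted SGCA pairs the female component of the female
parent with the male component of the male parent, the only pairing
that uses the partition's direction. A trend test (200 simulations with
reciprocal deviations and no maternal effects) checks that the adjusted
SCA correlates with hybrid means at least as strongly as Griffing's SCA
on average, which is the qualitative behaviour that motivates the
partition.

## The simulator and what it does (not) emulate

`sim_truth()` fixes a Model I truth: grand mean, centred blocks, GCA
`g`, maternal `m` (female side `g+m`, male side `g−m`), symmetric SCA
with zero row sums, antisymmetric non-maternal deviations with zero row
sums, optional self-depression offset on the diagonal, and i.i.d.
normal plot error. Supplied effects are projected into that constraint
space, which is exactly the estimators' parameter space — hence with
`sigma_e = 0` the full pipeline returns the generating values to
machine precision (tested), and the recovery experiment's estimands are
well defined. The default scenario mirrors a realistic maize
grain-yield trial: p = 8, r = 3, µ = 70 q/ha, plot error variance
≈ 47.6 (`sigma_e = 6.9`), GCA spread ≈ 3.5, maternal spread ≈ 5.5, SCA
spread ≈ 12, non-maternal spread ≈ 6 q/ha. These were chosen once to
match the scale of published 8-parent maize diallels and are not tuned.

The generator emulates a balanced single-environment RCBD with
homoscedastic normal error. It does not emulate genotype × environment
interaction, unbalanced or missing plots, spatial field trend,
non-normal error, or epistasis beyond what the SCA matrix absorbs —
so passing recovery tests demonstrate correctness of the estimators
under the model's own assumptions, not robustness to violations of
them.

Problem sizes used by the test suite — 10,000 error-only draws for the
standard-error check, 1,000 null simulations for the maternal-F size,
2,000 trials for component recovery, and 4–8-parent tables for the
algebraic property loops — keep the whole suite under a minute on one
core while leaving Monte-Carlo error well inside the asserted bands.

## Numerical and interface choices

* Input is long-format CSV (`female,male,rep,<traits...>`), UTF-8,
  1-based integer `rep`, opaque parent labels. Completeness
  (all p²·r triples), uniqueness and numeric traits are hard errors —
  no imputation, because every closed form assumes a balanced table.
  Records outside the declared parent set (e.g. commercial check
  varieties grown alongside) are rejected rather than dropped.
* Entries are means over replications; marginal "totals" are totals of
  entry means, which is what makes the treatment df p² − 1 with selfs
  included.
* The layout is treated as a randomized complete block design (blocks =
  replications); a single replication is accepted for data handling but
  refused by the ANOVA (no residual df).
* Human-readable report tables round to 2 decimals; the JSON companion
  keeps 17 significant digits so a reload is bit-for-bit.
* F-statistics with a zero error term are refused (`ms_residual > 0`
  is required); zero-variance effect classes simply yield zero SS and
  empty stars. Undefined ratios (Baker with no genetic variance,
  heritability with zero σ²P, correlation of a constant series) are
  reported as 0 / missing rather than NaN.
* Partial diallels (Griffing Methods 2–4), Model II/REML fitting,
  multi-environment analysis and Hayman graphical analysis are out of
  scope.

## Worked pipeline

```{r example}
truth <- sim_truth(p = 8, r = 3, seed = 2024)
d <- simulate_diallel(truth)
fit <- diallel_analyze(d)
fit$traits$trait$anova
round(rbind(g_mi = fit$traits$trait$partitioned$g_m,
            g_fi = fit$traits$trait$partitioned$g_f,
            m_i  = fit$traits$trait$partitioned$m), 2)
fit$traits$trait$genetics
```

A small recovery run (larger runs back the package's validation):

```{r recovery}
recovery_experiment(truth, n_sims = 50, seed = 7)
```
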