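---
title: "Models and methods behind mutscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
```

mutscreen analyses replicate-vial mutation screens for life span: many
single-mutation lines in a co-isogenic background, phenotyped alongside
the unmutagenized control. This vignette documents the statistical models
the package fits, the choices made where the designs admitted more than
one defensible construction, and what the synthetic-data generator does
and does not emulate.

## The data model

A survival table has one row per fly: `block`, `line`, `sex`, `vial`,
`death_age`. Death ages sit on a census grid — deaths are scored at the
census on or after true death, and the recorded census day *is* the
lifespan (no midpoint correction), because that is how such screens log
mortality. The census interval (default 2 days) and its start are
configurable. Sex has exactly two levels; vials are unique within
line × sex × block; unbalanced designs (missing vials, unequal replicate
counts) are accepted everywhere downstream. Flies that escape or are
lost during transfer are not modelled: there is no censoring support,
because in-protocol every fly is followed to death.

Line-level inference works on *vial means* (`vial_means()`), and effects
are expressed as *deviations from the contemporaneous control*
(`deviations_from_control()`): the control mean is computed per sex
within the same experimental block, never across blocks, since blocks
are separated in time and conditions.

## Variance components and heritability

The pooled model on vial means is `Y = μ + L + S + L×S + ε`, with line
random, sex fixed (unrestricted mixed-model convention) and ε the
between-vial residual; per-sex analyses use `Y = μ + L + ε`. Sums of
squares are sequential (Sex, then Line, then L×S), computed by projection
onto nested model spaces.

Method-of-moments components solve the expected-mean-square equations.
For balanced data these are the textbook coefficients (e.g.
`E[MS_L] = σ²_ε + r σ²_SL + 2r σ²_L` with `r` vials per sex); for
unbalanced data the coefficients are derived from the actual design by
Hartley's method of synthesis — each random-effect indicator column is
run through the same sequential quadratic forms, giving
`tr(Q_t Z_k Z_kᵀ)/df_t` exactly. This generalises Henderson's
method-of-moments approach to arbitrary missingness and reduces to the
closed forms on balanced data (both facts are tested). Negative
estimates are truncated to zero after solving, with a warning and a flag
in the output, before any ratio is formed.

Heritability is the broad-sense ratio
`H² = (σ²_L + σ²_SL)/(σ²_L + σ²_SL + σ²_ε)`; the cross-sex genetic
correlation divides either the directly estimated cross-sex covariance
of line means (default when available) or the pooled-model σ²_L by the
product of per-sex line SDs. Both numerator conventions are offered
because published tables use both, and with strictly positive per-sex
components they bracket the same quantity.

**F-ratio convention.** Every term is tested over the error mean square
by default. A conservative mixed-model test of Line would use the L×S
mean square as denominator, and `two_factor_mixed_anova(denominator =
"interaction")` provides it; the error-MS convention is the default
because it is what large published screen tables print, and the
denominator map is explicit in `anova_table()` rather than buried in the
engine.

The secondary (confirmation) screen model on individuals,
`Y = μ + L + S + L×S + R(L×S) + ε`, separates the replicate-vial stratum
from within-vial error; Line, Sex and L×S are tested over the replicate
mean square, matching the design's randomization (vials, not flies, are
the independent units for line effects).

## The CI and Dunnett screens

The CI screen flags a line when its deviation exceeds `z_α σ/√n`, with
z = 1.96 / 2.575 / 3.3 at 95 / 99 / 99.9%, σ the phenotypic SD of a vial
mean implied by the fitted components, and n the replicate vials behind
the deviation (4 pooled, 2 per sex under the default screen design). The
boundary is strict — a deviation exactly equal to the half-width is not
significant — a choice the method leaves open; ties have probability
zero in theory and the strict rule is the conservative one. Note the
method treats the control mean as known; with only ~10 control vials per
sex the realized null flag rate is inflated above the nominal 5% (to
roughly 7%), which is a property of the method, not of the
implementation — the calibration tests therefore use a heavily
replicated control.

Dunnett's many-to-one test is computed from the joint multivariate-t
distribution of the line-vs-control t statistics, whose correlation is
the product structure `ρ_jk = λ_j λ_k`, `λ_j = √(n_j/(n_j+n_0))`; this
is exact under unequal replicate counts, and the integral is evaluated
by the Genz–Bretz Monte-Carlo algorithm with a fixed, user-settable
seed. Tests are two-sided (the screen looks for both directions; the
published analyses do not state sidedness). The package reports CI and
Dunnett verdicts separately and offers
`combine_screen_verdicts(method = "union")` (default) or
`"intersection"`, since the rule by which published screens combine the
two methods is not specified.

## Sex-effect classification

`classify_sex_effect()` maps the significance pattern (pooled L, L×S,
per-sex L) to a category. The core rules: no interaction + significant
L → *both sexes*; interaction + one responsive sex → *sex-specific*;
interaction + both sexes responsive → *sex-biased* when pooled L is
significant and the effects agree in sign, *sex-antagonistic* when
pooled L is not significant or the per-sex effects oppose in sign.
Three refinements were needed to make the verbal rule total and
faithful to how screens actually categorize lines:

1. With neither pooled term significant but exactly one sex significant,
   the line is classified sex-specific (the pooled test can lack power
   when only one sex responds).
2. When the interaction is significant, a marginal (0.05 < P < 0.1)
   separate-sex term counts as responsive for deciding whether *both*
   sexes react (`alpha_marginal = 0.10`).
3. Opposite-sign per-sex effects, when effect sizes are supplied, force
   *sex-antagonistic* even if the pooled L term reaches significance —
   opposing effects can partially cancel in the pooled analysis, or
   leave a significant pooled term when one sex dominates, and P values
   alone cannot distinguish this from a biased response.

With these rules the classifier reproduces, from the published
significance patterns, the full 58-line category column of the screen
table shipped in `inst/extdata/` (17 both sexes, 22 male-specific, 9
female-specific, 2 + 2 biased, 6 sex-antagonistic). The classifier is
symmetric under swapping the sexes; ties in the biased direction are
broken by the larger absolute effect.

Revertant comparisons use Tukey–Kramer studentized-range tests on group
means with a pooled error MS and an insert-and-absorb compact letter
display: groups share a letter exactly when not significantly different.

## Half-diallel combining abilities

For all pairwise crosses of n mutant lines (no selfs, no reciprocals —
Griffing Method 4 — with parents fixed — Model 1), GCA and SCA are the
closed-form estimates

```
GCA_i  = T_i/(n−2) − ΣT/[n(n−2)]
SCA_ij = X_ij − (T_i + T_j)/(n−2) + ΣT/[(n−1)(n−2)]
```

which coincide with the constrained least-squares fit of
mean + additive + interaction effects on the cross means (tested against
an independent normal-equations oracle), satisfy ΣGCA = 0 and vanishing
off-diagonal row sums of SCA exactly, and reconstruct every cross mean
as `grand mean + GCA_i + GCA_j + SCA_ij`. Standard errors are the
classical Model 1 forms `Var(GCA_i) = (n−1)/[n(n−2)] σ²_m` and
`Var(SCA_ij) = (n−3)/(n−1) σ²_m`, with σ²_m the error variance of a
cross mean from the replicate-vial stratum; both constants were verified
by direct coefficient algebra before being frozen into the code.
Published diallel analyses of this kind were run through SAS macros
whose exact SE constructions are not printed, so the classical Griffing
forms are the documented reference here.

The ANOVA partitions the genotype term (df `n(n−1)/2 − 1`) into GCA
(df n−1) and SCA (df n(n−3)/2) by sequential projection — additive
design first, then the full cross factor — so `SS(G) = SS(GCA) + SS(SCA)`
holds identically; sex interactions (GCA×S, SCA×S) follow the same
scheme, and all terms are tested over the replicate stratum. Incomplete
half-diallels are rejected rather than imputed: the closed forms assume
completeness.

Epistasis calls: each SCA with two-sided t-test P below α becomes a
network edge, enhancing if positive (double heterozygote longer-lived
than its GCA expectation), suppressing if negative. A valid SCA matrix
cannot contain isolated nonzero cells — the row-sum constraint forces
small compensating entries — so planted-signal tests check that all
planted edges are recovered with correct signs and that false calls stay
near the per-cell α, rather than demanding exact support recovery, which
the constraint geometry makes impossible at conventional α.

## Pleiotropy correlations

`mutational_correlations()` computes Pearson correlations of line-mean
deviations per trait pair within each sex × age cell, with
pairwise-complete deletion (traits are routinely measured on different
line subsets, which is what produces dfs of 48 vs 38 at 50 lines),
`se = √((1−r²)/df)`, `t = r/se` and a two-sided t test against zero.
Cells with fewer than 3 complete pairs are flagged inestimable. Chill
coma recovery is analysed on raw recovery time; any
"shorter-time-is-fitter" recoding is a presentation choice left to
report writers.

The test against unity uses the Fisher z transform against a fixed
boundary ρ₀ = 0.999: `z = (atanh r − atanh ρ₀)√(df−1)`, one-sided. An
exact test at ρ = 1 does not exist (the transform diverges and the
sampling variance collapses), so a just-below-one boundary makes the
test well defined while remaining conservative: P is monotone in r and
approaches ½ as r approaches the boundary.

## The synthetic-data generator

The generator is the package's stand-in for the screen conditions.
Defaults (all configurable):

| parameter | default | units | rationale |
|---|---|---|---|
| μ | 55 | days | typical control life span in such screens |
| σ²_L, σ²_SL | 30, 25 | days² | line and line×sex components at the magnitudes large screens report |
| σ²_vial | 25 | days² | vial-to-vial micro-environment; not identifiable from published tables, chosen so vials contribute about half the vial-mean error |
| σ²_error | 100 | days² | within-vial individual variance (SD 10 d) |
| design | 2 vials × 5 flies per sex | | the initial-screen layout |
| sex effect | +2 | days | small female−male difference |
| census | 2 | days | the screen's census interval |

On the vial-mean scale the residual is σ²_vial + σ²_error/5 = 45 days²,
so the default triple (30, 25, 45) matches the component magnitudes the
estimators are expected to recover; parameter-recovery tests at 500
lines × 2 sexes × 2 vials × 5 flies over 20 replicates require the
Monte-Carlo mean of each component within 15% and H² within 0.05 of
truth. Line and interaction effects are drawn normal (the CI screen
assumes normality); lifespans are snapped *up* to the census grid and
truncated below at one census interval so no age is non-positive.

All randomness flows from one integer seed through a single stream with
a fixed drawing order (line effects → line×sex → vial → individual), so
identical seeds give identical tables; subsets are reproduced by
regenerating and slicing rather than by per-unit substreams — one stream
keeps the generator simple and the order is documented, which serves the
same audit purpose. Ground truth is returned as a sidecar object, never
embedded in the data.

The diallel generator produces replicate vial means with expectation
`μ ± sex/2 + g_i + g_j + s_ij ± (sg_i + sg_j + ss_ij)` for the 45
crosses of the default 10 parents, 8 vials per cross per sex; the
pleiotropy generator draws multivariate-normal line deviations with any
user-specified PSD covariance (rank-deficient accepted).

What the generator does **not** emulate: Gompertz/Weibull mortality
curvature (analyses here are of means, not hazard shapes), block
structure and block×line interaction, non-normal or skewed line-effect
distributions, census-grid heaping beyond the snap rule, and escapes or
censoring. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to every feature
of real screen data.

## Numerical choices and problem sizes

- Sequential SS via QR projections; EMS coefficients by synthesis on the
  same QR factors; EMS systems solved densely (3×3).
- Dunnett integrals: Genz–Bretz with absolute tolerance 1e-4 and a fixed
  seed; adjusted P is floored at the unadjusted P.
- Tukey letters: `ptukey` with Tukey–Kramer SEs; zero error MS with
  unequal means is an error (degenerate tests).
- Truncation of negative components happens once, after solving, before
  ratios; truncation is flagged.
- Test-suite problem sizes were chosen to estimate each property with
  comfortable Monte-Carlo margins while keeping the default run light:
  20 × 500-line screens for component recovery, 500 simulations each for
  the Dunnett familywise and SCA null calibrations, 20 × 250-line null
  screens for the CI flag rate, 40 planted-signal diallels.

## Known limitations

- Method-of-moments (not REML) is the reference estimator; for severely
  unbalanced designs REML would be more efficient, and no
  likelihood-ratio tests or Satterthwaite dfs are provided.
- The exact EMS coefficients of historical SAS analyses of unbalanced
  screens cannot be reconstructed from printed tables, so re-derived
  components will approximate, not equal, older published σ² values;
  printed F ratios and heritability arithmetic are reproduced exactly.
- Dunnett P values for very many comparisons (hundreds per block) rely
  on Monte-Carlo integration; absolute accuracy ~1e-3.
- No FDR machinery: the screening methods here are CI bands and
  familywise Dunnett control, as appropriate for phenotype screens with
  a common control.
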