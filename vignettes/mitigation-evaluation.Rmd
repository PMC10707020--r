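---
title: "Multi-trait comprehensive evaluation of stress-mitigation treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait comprehensive evaluation of stress-mitigation treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mitieval)
```

## The problem

Maize sown deep (around 20 cm, an arid-land practice that places seed in
moist soil) emerges poorly: the mesocotyl and coleoptile must elongate far
more than at a normal 3 cm depth, and seedlings that do emerge are slender
and weak. Exogenous serotonin (5-HT) applied in the sowing matrix can
partially relieve this deep-seeding stress, but its effect is dose-dependent
and spread over many correlated phenotypes — emergence, biomass, elongation,
tissue thickness, IAA, H2O2 and lignin levels in the mesocotyl and
coleoptile. Deciding which dose mitigates best therefore requires a
composite criterion over all traits, not a per-trait significance test.

`mitieval` implements such a comprehensive evaluation for a design with two
controls and a dose ladder: an unstressed control `CK+` (3 cm, no 5-HT), a
stressed control `CK-` (20 cm, no 5-HT), and treatments `T1`–`T5` (20 cm
with 1.0, 1.5, 2.0, 2.5, 3.0 mg/L 5-HT), five replicates per treatment, 30
seeds per emergence device, and 17 traits.

## The evaluation chain

**Mitigation effect index.** For trait $i$ and dose treatment $T_n$, with
treatment-level cell means $T_{i\cdot}$,

$$
MEI_{i,T_n} =
\frac{T_{i,T_n} - T_{i,CK-}}{\lvert T_{i,CK+} - T_{i,CK-} \rvert}
\quad\text{(traits where larger = more tolerant)},
$$
$$
MEI_{i,T_n} =
\frac{T_{i,CK-} - T_{i,T_n}}{\lvert T_{i,CK+} - T_{i,CK-} \rvert}
\quad\text{(traits where smaller = more tolerant)}.
$$

The index is 0 when a dose leaves the trait at its stressed value and 1 when
it moves the trait by the full stress-induced gap; it is deliberately not
clipped — doses can overshoot (MEI > 1) or backfire (MEI < 0). Because the
direction switch is applied here, a larger MEI always means stronger
mitigation, for every trait.

**Membership function.** Within each trait's scope the MEIs are min–max
rescaled to $[0,1]$:
$U_{i,T_n} = (MEI_{i,T_n} - MEI_{i,\min}) / (MEI_{i,\max} - MEI_{i,\min})$.

**Comprehensive score.** $U_{T_n}$ is the unweighted mean of the 17
membership values of a (genotype, treatment) cell; treatments are ranked on
the mean of $U_{T_n}$ across genotypes, the coefficient of variation
($100\,s/\bar x$) is computed over all genotype × treatment scores, and the
optimum is the argmax (exact ties are reported as a set, never broken by
index order).

```{r}
tab <- generate_trait_table(deepseed_preset(cv_percent = 0), seed = 1)
fit <- mitigation_eval(tab)
fit
```

## Design choices that were genuinely open

**Direction handling (`direction_mode`).** The membership-function pair is
stated in the literature with a complementary form ($1 - U$) for negatively
correlated traits, but the MEI already orients negative traits so that
larger means better. Applying the complementary form after the oriented MEI
would invert those traits twice, making doses that demonstrably lower H2O2
and lignin score *worse*. The default mode `"oriented"` therefore applies
the plain min–max form to every trait; `"literal"` is available to
reproduce the double-inversion reading. The package treats this as the
method's main interpretational fork and exposes both.

**Normalization scope (`scope`).** Whether $MEI_{i,\min/\max}$ are taken
within each genotype (`"per-genotype"`, the default — "under all
treatments" is read as the five doses of one line) or pooled across
genotypes (`"pooled"`). Both are implemented; under the calibrated preset
both select the same optimum. A useful consequence of per-trait min–max
scoping: the score is invariant to the per-trait denominator
$\lvert CK+ - CK- \rvert$, so near-degenerate stress gaps distort single
MEIs but not the ranking.

**Trait directions.** The 17-trait registry defaults to *positive* for
emergence, seedling length/weight, mesocotyl and coleoptile length, coarse
and weight, total length, and IAA in both tissues, and *negative* for H2O2
and lignin in both tissues and for the mesocotyl-to-coleoptile ratio
(stress inflates it; mitigation brings the architecture back toward the
unstressed proportion). Directions are never hard-coded into the math and
can be overridden per trait from a YAML/JSON file
(`read_direction_override()`), because reasonable analysts could disagree
about the ratio trait in particular.

**Degenerate cases.** A stress gap $\lvert CK+ - CK- \rvert$ at or below
$10^{-12}\max(\lvert CK+\rvert,\lvert CK-\rvert,1)$ is an error by default
(the trait carries no stress signal to mitigate), with an opt-in `"drop"`
policy; a constant-MEI membership scope is likewise an error with an opt-in
midpoint (0.5) policy. Missing cells are hard errors — the comprehensive
score is only meaningful over the complete trait set.

## The synthetic-data generator

No replicate-level data are deposited with the source study, so the
generator is the package's test bed and its defaults *are* the study
conditions: 2 genotypes (ly119-2, ZRX87-1) × 7 treatments × 17 traits × 5
replicates. `deepseed_preset()` encodes, in normalized units (unstressed
control = 1), every published fold-change and percent change of the
phenotyping results: stress ratios $CK-/CK+$ per trait, and dose ratios
$T_n/CK-$ where printed. Examples: ly119-2 seedling weight falls to 0.423
of control under stress and T4 restores 2.42× the stressed value; mesocotyl
H2O2 rises 2.81× under stress and T4 removes 67.49% of it.

Dose cells that were never printed (most traits outside the best dose) are
filled by a quadratic on the log-ratio scale through zero at dose 0 with
its peak at the *anchored* (printed-best) dose — 2.5 mg/L for most traits,
but 2.0, 1.5, 1.0 or 3.0 mg/L for the few traits whose published best dose
differs. These cells are tagged `interpolated` so tests can restrict
exact-ratio assertions to printed cells. Two values are tagged `assumed`:
the unstressed-control emergence rate (100%, never printed) and a small
non-significant coleoptile-weight change under stress (ratio 0.95; the
source reports "no impact", and an exact ratio of 1 would make the MEI
denominator degenerate — the score is invariant to this choice).

Two identities are enforced by construction, not by sampling: total length
= mesocotyl + coleoptile length and the mesocotyl-to-coleoptile ratio are
computed per replicate from the generated component lengths. The published
per-treatment ratios for these two derived traits are internally
inconsistent with their components (the printed T4 total-length gain lies
below both component gains), so the components are taken as authoritative;
the coleoptile baseline per genotype is solved so the derived
stressed-control ratios match the printed ones.

Noise: replicate values are truncated-normal (positive) with a per-trait
standard deviation of `cv_percent` (default 10%, a typical seedling-assay
replicate CV; the source reports no replicate dispersion) times the cell
mean; a lognormal option exists. Emergence is Binomial(30, p)/30 per device
on the percent scale; with `cv_percent = 0` every replicate equals its cell
mean exactly, emergence included. The Ct generator produces the 8 target
genes (4 IAA-pathway, up-regulated; 4 lignin-pathway, down-regulated) plus
the Actin 1 reference, with effects in cycles (defaults: 1.5 cycles for
stress, 1 further cycle at the 2.5 mg/L dose, 0.3 cycles Gaussian replicate
noise, 3 qPCR replicates).

What the generator does *not* emulate: trait–trait correlation beyond the
two constructed identities (replicates are drawn independently per trait),
genotype × environment interaction structure beyond the calibrated means,
spatial/device effects, and any mechanistic link between Ct values and the
phenotypes. Pipeline tests that pass on this generator therefore validate
the arithmetic and the decision rule under the published mean structure,
not the field behaviour of real seedlings.

## Supporting analyses

- `pearson_matrix()`: product-moment correlation with two-sided p from the
  t-distribution on $n-2$ df; constant columns are flagged, their pairs NA;
  significant pairs counted at p < 0.05.
- `trait_pca()`: eigen-decomposition of the trait correlation matrix
  (traits mix %, cm, g, ng g⁻¹ FW, µM g⁻¹ FW, A₂₈₀ g⁻¹ — a covariance PCA
  would be dominated by unit choices; covariance mode is behind a flag).
  Retention is strict eigenvalue > 1.0; loadings are eigenvector entries,
  sign-fixed (largest entry positive), no rotation.
- `upgma_cluster()`: between-group (average-linkage) agglomeration on
  Euclidean distance via `stats::hclust`, with rows label-sorted first so
  the result is order-invariant; `cut_dendrogram()` cuts by height or k;
  Newick export via `ape`.
- `relative_expression()`: per replicate, $\Delta Ct = Ct_{target} -
  Ct_{ref}$ and expression $2^{-\Delta Ct}$; replicates are averaged on the
  expression scale by default (matching replicate-level error bars), with a
  Ct-first averaging flag — the two differ by Jensen's inequality.

The published multivariate summaries that depend on the unavailable raw
table (90.735% variance over four PCs, 98 significant trait pairs, the
cluster cut at distance 5.2) are not reproducible from calibrated means and
are not asserted anywhere; the analyses themselves are oracle-tested on
synthetic matrices.

## Problem sizes and runtime

The default study size (2 × 7 × 17 × 5 = 1190 observations) evaluates in
well under a second. The dose-recovery study in the tests and acceptance
script uses 200 seeded generator runs at 10% replicate CV (about half a
minute in total); the law-of-large-numbers check uses 400 replicates per
cell for one genotype. These sizes were chosen to make Monte Carlo
assertions stable at the 95% recovery threshold.

## Known limitations

- The comprehensive score is unweighted; traits enter with equal weight
  regardless of their redundancy (11 of the 17 are length/biomass-family
  traits). A PCA-weighted variant would be a natural extension but is
  intentionally out of scope.
- MEI is computed on cell means; replicate uncertainty does not propagate
  into U. The generator plus repeated seeds is the supported way to assess
  decision stability.
- The min–max membership makes U sensitive to the worst and best dose in
  the scope; adding or removing a dose changes all scores of its trait.
- With only five doses, "optimum" means best of the ladder, not a fitted
  dose-response maximum.
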