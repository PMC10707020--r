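# mitieval

Multi-trait comprehensive evaluation of stress-mitigation treatments for
seedling phenotyping experiments, built around the deep-seeding maize
design: an unstressed control (`CK+`, 3 cm sowing depth), a stressed
control (`CK-`, 20 cm) and a ladder of serotonin (5-HT) doses `T1`–`T5`
(1.0–3.0 mg/L at 20 cm), scored over 17 traits in two inbred lines.

## The method

For each trait *i* and dose treatment *Tn*, the **mitigation effect index**
compares cell means against both controls, with a direction switch so that
a larger index always means stronger mitigation:

    MEI(i,Tn) = [T(i,Tn) − T(i,CK−)] / |T(i,CK+) − T(i,CK−)|   (positive traits)
    MEI(i,Tn) = [T(i,CK−) − T(i,Tn)] / |T(i,CK+) − T(i,CK−)|   (negative traits)

MEIs are min–max rescaled within each trait's scope by the **membership
function** U(i,Tn) = [MEI − MEI_min] / [MEI_max − MEI_min], and the
**comprehensive score** U_Tn is the unweighted mean of a cell's 17
membership values. Treatments are ranked on the mean U across genotypes;
the coefficient of variation and the optimum dose (ties reported, never
broken arbitrarily) complete the report.

Supporting modules: Pearson trait correlation with t-distribution
p-values, correlation-matrix PCA with strict eigenvalue > 1 retention,
between-group (UPGMA) clustering with Newick export, 2^−ΔCt relative
expression from qPCR Ct tables, and a seeded synthetic-data generator
whose built-in preset is calibrated to the published fold-changes of the
deep-seeding serotonin study (noise-free runs reproduce every printed,
non-derived ratio exactly).

## Worked example

```r
library(mitieval)

tab <- generate_trait_table(deepseed_preset(cv_percent = 0), seed = 1)
fit <- mitigation_eval(tab)
fit
#> Multi-trait mitigation-effect evaluation
#>   genotypes:   ly119-2, ZRX87-1
#>   traits:      17
#>   treatments:  T1, T2, T3, T4, T5
#>
#> Comprehensive mitigation evaluation (17 traits, oriented mode, per-genotype scope)
#>
#> Mean comprehensive score by treatment:
#>  treatment dose_mg_per_L mean_u rank
#>         T4           2.5 0.9168    1
#>         T3           2.0 0.7520    2
#>         T5           3.0 0.5033    3
#>         T2           1.5 0.3964    4
#>         T1           1.0 0.1171    5
#>
#> Optimum: T4 (2.5 mg/L), mean U = 0.917, margin 0.165
#> CV of U over 10 cells: 55.4%
```

The ranking says that, integrating emergence, growth, IAA, H2O2 and lignin
responses of both genotypes, the 2.5 mg/L dose (T4) mitigates 20 cm
deep-seeding stress best, with 2.0 mg/L second — the doses below 2.0 mg/L
recover little of the stress gap. `coef(fit)` returns the per-cell scores,
`summary(fit)` adds the membership scope audit, `plot(fit)` draws the
grouped score bars. `run_pipeline()` writes every stage (means, fold
changes, MEI + provenance, membership, scores, correlation/PCA/dendrogram,
expression) to CSV/Newick/JSON for a full reproducible run.

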