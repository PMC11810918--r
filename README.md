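# mhpheno

Data-driven mental-health phenotyping for cohorts of people with HIV (PWH),
from item-level questionnaire responses to explainable classification.

Mental-health symptom burden in PWH is heterogeneous: depression, anxiety
and PTSD symptoms co-occur in profiles that a single total score cannot
distinguish. This package implements a three-step phenotyping analysis for
epidemiologists and clinical researchers working with self-report
questionnaires:

1. **Phenotype discovery.** Score the PHQ-9, BAI and PCL-C; embed the
   n×3 matrix of totals with UMAP; cluster the embedding with HDBSCAN
   (noise-aware, no preset cluster count); validate with silhouette; name
   clusters with a deterministic clinical rubric (PTSD / anxiety / mixed
   anxiety–depression / minimal symptom).
2. **Referent-cluster inference.** Welch *t*-tests (continuous) and Pearson
   χ² tests (categorical) of each phenotype against the minimal-symptom
   referent, on demographics, viral load and Childhood Trauma Questionnaire
   adversity categories — from raw data or from published summary
   statistics.
3. **Explainable classification.** A gradient-boosted tree classifier
   (logistic loss, sigmoid link, 0.5 boundary) separating the PTSD from the
   minimal-symptom phenotype, with Pearson-r > 0.65 redundancy groups
   resolved by the maximal information coefficient (MIC), optional two-way
   product/quotient interaction features, greedy forward selection under
   the 1-SD model-saturation rule, stratified 5×5-fold cross-validated F1,
   partial-dependence curves and pairwise interaction surfaces.

Because raw cohorts of this kind are typically restricted, the package also
ships a **seeded synthetic-cohort generator** calibrated to published
per-cluster summary statistics of a Ugandan PWH cohort (n = 277, four
phenotypes at prevalences 27/12/47/14%), with exact item–total
conservation, planted item-level signatures and known-truth labels for
recovery testing. See the methods vignette
(`vignettes/phenotyping-methods.Rmd`) for the models, defaults and design
rationale.

## Worked example

```r
library(mhpheno)

cohort   <- generate_cohort(cohort_config(seed = 2))  # 277 synthetic PWH
scored   <- score_cohort(cohort)                      # totals, bands, flags
solution <- phenotype_clustering(scored, embedding_config(seed = 2))
print(solution)
```

```
<cluster_solution> 4 clusters over 277 participants; silhouette = 0.758
 cluster   n bai_mean bai_sd phq9_mean phq9_sd pclc_mean pclc_sd                phenotype
       1 148    1.284  1.240   1.14865  1.2419     21.68  1.9624 mixed_anxiety_depression
       2  58    7.931  5.537   4.41379  3.9914     38.05  6.2896                     PTSD
       3  41    0.000  0.000   0.02439  0.1562     17.07  0.2637          minimal_symptom
       4  30    5.067  1.172   3.40000  0.8944     20.73  1.4126                  anxiety
```

The four phenotypes emerge with a mean silhouette of 0.76: a PTSD cluster
(mean PCL-C 38, above the clinical threshold of 33), an anxiety cluster
(elevated BAI at 5.1, older members), a large mixed anxiety/depression
cluster, and a minimal-symptom cluster at the instrument floors. Referent
comparisons against the minimal-symptom cluster:

```r
ref_cl <- as.integer(names(which(solution$phenotypes == "minimal_symptom")))[1]
comparisons <- compare_to_referent(scored, solution$labels, referent = ref_cl)
subset(comparisons, variable %in% c("age", "ctq_sa_cat"))
```

```
 cluster   variable               test statistic       df p_display
       1        age            welch_t 1.7535703 65.54469      0.08
       1 ctq_sa_cat pearson_chi_square 0.5714883  2.00000      0.75
       2        age            welch_t 0.6673669 91.97013      0.51
       2 ctq_sa_cat pearson_chi_square 6.2739426  2.00000      0.04
       4        age            welch_t 3.9834693 66.85917    <0.001
       4 ctq_sa_cat pearson_chi_square 1.6635746  2.00000      0.44
```

The PTSD cluster (2) shows the planted excess of childhood sexual abuse
relative to the minimal-symptom referent (χ², df = 2, p = 0.04), and the
anxiety cluster (4) is significantly older (Welch *t*, p < 0.001) — the
qualitative pattern the generator was calibrated to. The classification
step and its explanation products:

```r
report <- classify_phenotypes(scored, solution$phenotype, seed = 2)
report$mean_f1          # cross-validated F1 (25 trials) for PTSD vs minimal
report$features         # features surviving saturation-based selection
report$pdp              # partial-dependence tables per selected feature
```

`run_pipeline(run_config(...))` chains the stages end-to-end (simulate →
score → cluster → profile → compare → classify) with a manifest of
artifacts, seeds and checksums; `inst/scripts/mhpheno-cli.R` is a thin
command-line wrapper with the same verbs.

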