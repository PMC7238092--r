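# quadriplanes

Decision fusion and reader-study evaluation for multi-plane breast-ultrasound
CAD.

Breast-ultrasound CAD modules (such as S-Detect) return one dichotomous
"possibly benign"/"possibly malignant" call per stored imaging plane of a
lesion. How those per-plane calls are fused determines the operating point of
the system: the **cross-planes** rule reads the longitudinal and transverse
planes and calls the lesion positive if *either* plane is positive (high
sensitivity, weak specificity), while the **quadri-planes** rule adds two
oblique planes at 45° and requires **at least 2 of 4** positive planes. In the
*combined* reading mode, a reader's BI-RADS category (3, 4A, 4B, 4C, 5) is
adjusted one level up when the fused CAD verdict is positive and one level
down when every plane is benign, then dichotomized at the 4A/4B boundary
(4B/4C/5 positive for cancer).

The package provides:

- the fusion rules (`fusion_rule()`, `cad_standalone_verdict()`), the
  one-level category adjustment (`adjust_category()`,
  `combined_mode_verdict()`) and the BI-RADS scale helpers;
- the paired diagnostic-accuracy toolkit: exact-ratio 2×2 metric panels
  (`metrics_from_table()`), exact and continuity-corrected McNemar tests
  (`mcnemar_test()`), Cohen's κ with the standard agreement bands
  (`cohen_kappa()`), empirical ROC curves over ordinal scores with
  tie-corrected AUC (`empirical_roc()`), the Hanley–McNeil standard error
  SE²(A) = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)]/(n₊n₋) and correlated-AUC
  z-comparison (`hanley_mcneil_se()`, `compare_auc_paired()`), Youden-index
  cutoffs at score midpoints (`youden_optimal()`), and two-proportion tests
  (`compare_proportions()`);
- a calibrated synthetic-cohort generator (`simulate_cohort()`) with
  correlated per-plane calls (equicorrelated latent Gaussian thresholding,
  exact marginals at any correlation) and ordinal-probit reader scores
  sharing a latent severity;
- an end-to-end pipeline (`evaluate_modes()`, `decision_change_audit()`,
  `read_cohort_csv()`, `write_report()`) plus packaged fixtures carrying the
  reference reader study's printed contingency tables (512 lesions, 39.1%
  malignant) for exact reproduction of its metric panel via
  `reproduce_study()`.

## Worked example

Simulate a study-scale cohort under the default calibrated configuration and
evaluate every reading mode against pathology:

```r
library(quadriplanes)

cohort <- simulate_cohort(simulation_config(n_lesions = 512), seed = 42)
report <- evaluate_modes(cohort)
report
#> <study_report> 512 lesions (187 malignant, 325 benign)
#>                  mode sensitivity specificity  ppv  npv accuracy  auc
#>             cad_cross        85.6        70.2 62.3 89.4     75.8 0.83
#>            cad_quadri        81.3        81.5 71.7 88.3     81.4 0.89
#>        novice_without        59.9        86.8 72.3 79.0     77.0 0.81
#>       novice_combined        78.6        84.3 74.2 87.3     82.2 0.89
#>   experienced_without        75.4        94.8 89.2 87.0     87.7 0.92
#>  experienced_combined        86.6        87.4 79.8 91.9     87.1 0.93
```

The panel shows the expected structure: moving from the cross-planes to the
quadri-planes rule trades a few points of CAD sensitivity for ~11 points of
specificity, and the combined mode lifts each reader's sensitivity and
accuracy, with the largest gain for the novice. The quadri plane-count ROC
and the novice decision audit:

```r
report$modes$cad_quadri$roc
#> Empirical ROC: AUC = 0.8880 (SE 0.0168), 187 positive / 325 negative
#>   Youden J = 0.6282 at cutoff 1.50

report$decision_changes$novice
#> Decision changes across the 4A/4B boundary: 87
#>   4A->4B: 40 correct (malignant), 25 incorrect (benign)
#>   4B->4A: 17 correct (benign), 5 incorrect (malignant)
```

The cutoff is the midpoint between achievable plane counts (here ≥ 2 positive
planes of 4); J = sensitivity + specificity − 1 at that threshold. The audit
counts lesions whose category crossed the 4A/4B management boundary under CAD
adjustment: an upgrade 4A→4B is correct when the lesion is malignant, a
downgrade 4B→4A correct when benign.

Reproducing the reference study's tables from its printed counts:

```r
reproduce_study()$agreement
#>    novice_mode     kappa kappa_rounded     band
#> 1  without_cad 0.5648202          0.56 moderate
#> 2 combined_cad 0.6283490          0.63     good
```

Agreement between the experienced reader (without CAD) and the novice rises
from moderate to good once the novice reads in combined-CAD mode.

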