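# ssmpca

Voxel-wise phenotype differentiation for two-group 3-D imaging cohorts by
scaled subprofile modelling with principal component analysis (SSM/PCA).

## Who this is for

Imaging groups that have two clinically defined phenotypes (a reference
group and a target group), one or more co-registered scalar image
modalities per subject, and want a *single spatial pattern* whose
per-subject expression score separates the phenotypes — together with
honest answers to "is that pattern stable?" (bootstrap, leave-one-out
cross-validation) and "how well does it classify?" (Youden-ROC threshold,
sensitivity/specificity/PPV/NPV, two-modality concordance). The package
ships a synthetic brain-phantom cohort generator with a known embedded
pattern, so the whole pipeline is testable end to end without any clinical
data.

## The method

With in-mask, normalised subject profiles \(x_i \in \mathbb{R}^V\) and the
reference-group grand mean profile \(g = \bar{x}_{\text{ref}}\), the
residual profiles \(r_i = x_i - g\) form the matrix \(R\), decomposed in
subject space as \(R = U D V^\top\). Components (columns of \(V\)) are
retained as the smallest prefix whose cumulative variance accounted for,
\(\mathrm{VAF}_k = 100\, d_k^2/\sum_j d_j^2\), reaches 50%; stepwise-forward
logistic regression of group on the component scores selects the combining
subset, and the differentiating pattern is the slope-weighted component sum
at unit norm:

\( p \propto \sum_{k \in \text{sel}} \beta_k v_k, \quad \|p\|_2 = 1. \)

A subject's score is \(s_i = r_i^\top p\) (z-scored against the reference
training group). Stability is assessed by stratified bootstrap and by
LOOCV in which *every* stage is re-derived per fold; the classification
threshold maximises Youden's J on the cross-validated scores; held-out
validation subjects are projected and classified at that threshold; two
modalities combine by classification concordance (discordant subjects get
no call).

## Worked example

The `analysis/` scripts run the full study design on a simulated cohort of
30 reference + 20 target subjects (32³ grid, two modalities — an
intrinsically normalised quantitative map and a globally scaled weighted
contrast — sharing one embedded pattern):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_run_study.R
Rscript analysis/03_validation_tables.R
Rscript analysis/04_roc_concordance.R
```

`02_run_study.R` prints the study summary:

```
 modality pattern total_vaf bootstrap_success loocv_sustained       auc
     qmap    TRUE  68.82653               100            TRUE 0.9466667
      t1w    TRUE  68.99024               100            TRUE 0.9466667
 sensitivity specificity ppv npv validation_p
          87         100 100  88    0.4803275
          87         100 100  88    0.4803275
  concordance pair: qmap + t1w
  concordance: 100% of 50 subjects (50 concordant)
  within concordant: sens 90%, spec 100%, PPV 100%, NPV 94%
...
modality qmap: |cosine(pattern, truth)| = 0.986, total VAF 68.8%
modality t1w: |cosine(pattern, truth)| = 0.986, total VAF 69.0%
```

Reading this: for each modality a pattern was derived from the 15/15
training split whose selected components explain ~69% of residual
variance; it survives 1000-repetition bootstrap and LOOCV; the
cross-validated scores classify training subjects with AUC 0.95
(sensitivity 87%, specificity 100% at the Youden cut); and the derived
pattern is nearly collinear (cosine 0.986) with the ground-truth pattern
embedded in the phantom. The two modalities agree on every subject here
because they share the same simulated pathology — real multi-contrast
data will not be this concordant. Tables land in `results/`, pattern and
GMP volumes in `scratch/patterns/`.

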