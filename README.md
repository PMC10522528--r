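# gbmsurv

Glioblastoma (GBM) is the most aggressive primary malignant brain tumor,
with median overall survival around 14 months. Knowing *before* surgery
whether a patient is likely to survive less than one year, one to two
years, or more than two years would change surgical planning, trial
enrollment and shared decision-making. `gbmsurv` implements, end to end, a
survival-classification analysis that asks exactly that question of
preoperative imaging alone: resting-state functional connectivity,
contralesional cortical thickness, age and sex — no genetics, no treatment
variables.

The pipeline:

1. **Connectomics.** For 15 canonical resting-state networks (SMD, SMI,
   CON, AUD, DMN, PMN, VIS, FPN, SAL, VAN, DAN, MET, REW, THA, BGA), each
   with a 200-voxel ROI taken from the top of its probability map,
   similarity is measured by Szekely's distance correlation (V-statistic):
   with double-centered distance matrices `A`, `B` of two samples over the
   same `T` frames,

   ```
   dCov^2 = (1/T^2) * sum(A * B),   dCor = sqrt( dCov^2 / sqrt(dVar_X^2 * dVar_Y^2) )
   ```

   Between-network terms compare two 200-voxel blocks in one calculation;
   within-network terms average dCor(voxel, remaining 199 voxels) over
   voxels. All unordered network pairs (self-pairs included) give the
   120-element connectome vector `SMDxSMD, SMDxSMI, ..., BGAxBGA`.
2. **Compression.** A single-hidden-layer autoencoder (20 sigmoidal units,
   validation-terminated) encodes the 120 similarities; near-silent code
   units are pruned and the survivors become features `FC1..FCm`.
3. **Classification.** Age, sex, 34 cortical-thickness parcels and the
   encoded FC features feed a feedforward network (3 hidden layers x 8
   units, softmax over the three survival classes) trained under nested
   stratified cross-validation (10 outer / 5 inner folds) with a
   10-subject stratified global holdout and ensemble averaging.
4. **Attribution.** Permutation feature importance (accuracy drop under
   column permutation, out-of-fold) is traced from encoded features back to
   the 120 network pairs via absolute encoder weights, averaged per network
   (15 incident pairs each), and projected onto voxel probability maps.
5. **Reporting.** Kaplan-Meier curves and a log-rank test over the
   model-predicted groups, plus chi-squared / Kruskal-Wallis cohort tests.

Because no patient data can ship with the package, a first-class synthetic
cohort generator reproduces the *structure* the analysis assumes — group-
dependent network coupling, cortical thinning, demographic shifts and
class-consistent survival times — so every stage is testable and the whole
pipeline's ability to recover planted effects is measurable.

## Worked example

A desk-scale cohort with the default planted effects (cortical thinning of
0.15 mm per class, 4-year age shifts, three coupling pairs separating the
groups):

```r
library(gbmsurv)

cfg <- sim_config(n_subjects = 90, group_proportions = c(1, 1, 1) / 3,
                  voxels_per_network = 30, n_frames = 120, seed = 7)
cohort <- generate_cohort(cfg)
result <- run_experiment(cohort,
                         classifier = classifier_config(outer_folds = 5,
                                                        holdout = 9),
                         encoder = list(max_epochs = 1500),
                         importance_repeats = 50, seed = 7)
print(result)
#> GBM survival-classification experiment
#>  subjects: 90  features: 56  encoded FC: 20
#> CV accuracy:       100.0% (n = 81)
#> Holdout accuracy:  100.0% (pooled, n = 9)
#> Ensemble accuracy: 100.0% (averaged models)
#> Combined accuracy: 100.0%
#> Log-rank (predicted CV groups): chi2 = 149.56, df = 2, p = 3.33e-33
```

All four accuracies are perfect here because the planted effects are strong
and every class is balanced; the log-rank test confirms that the
*predicted* groups carry real survival separation. When the only group
signal lives in the three planted coupling pairs (no thinning, no age
shift), accuracy drops toward what functional connectivity alone supports
and the attribution stage finds the responsible pairs:

```r
cfg_fc <- sim_config(n_subjects = 120, group_proportions = c(1, 1, 1) / 3,
                     voxels_per_network = 30, n_frames = 160,
                     ct_group_shift = c(0, 0, 0),
                     age_mean_by_group = c(62, 62, 62),
                     sex_prob_by_group = rep(0.58, 3), seed = 11)
res_fc <- run_experiment(generate_cohort(cfg_fc),
                         classifier = classifier_config(outer_folds = 5),
                         encoder = list(max_epochs = 1500),
                         importance_repeats = 50, seed = 11)
print(res_fc$report)
#> CV accuracy:       57.3% (n = 110)
#> Holdout accuracy:  60.0% (pooled, n = 10)
#> Ensemble accuracy: 60.0% (averaged models)
#> Combined accuracy: 57.5%

round(head(sort(res_fc$importance$per_fc_pair, decreasing = TRUE), 5), 4)
#> SMIxDMN SMDxTHA SMDxCON VANxVAN SMDxVIS
#>  0.0201  0.0179  0.0156  0.0151  0.0140
```

The three planted pairs (`SMIxDMN`, `SMDxCON`, `SMDxVIS`) surface at ranks
1, 3 and 5 of 120, and the per-network averages put SMD on top — the
attribution chain (permutation importance on encoded features, absolute-
weight back-attribution, per-network averaging) recovers what was planted.

`run_pipeline(config, out_dir, seed)` runs the same stages from a single
configuration (R list or YAML), writes every artifact (`cohort.csv`,
`connectomes.csv`, `features.csv`, `predictions.csv`, `report.json`,
`importance.csv`, `km_curves.csv`, `tests.csv`) and returns an MD5
manifest; the same seed reproduces identical checksums.

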