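# mdsustain

Subtype and Stage Inference (SuStaIn) for cross-sectional, multimodal
biomarker data **with missing values**.

Progressive diseases are heterogeneous in two confounded ways: different
patients follow different progression patterns (*subtypes*), and at any
visit patients sit at different points along their pattern (*stages*).
SuStaIn disentangles the two by modelling each subtype as a strict
ordering of biomarker *Z-score events* — biomarker $i$ reaching
thresholds $Z_{i1} < \dots < Z_{iR_i}$ relative to a control population —
and staging every subject along its subtype's piecewise-linear
trajectory, all from a single cross-sectional visit.  Multimodal studies
(MRI volumes, CSF assays, PET, cognitive scores) almost always have
subjects missing at least one modality, which classical Z-score SuStaIn
cannot handle.  This package fits the model under the likelihood

$$
P(X \mid M) = \prod_{j=1}^{J} \sum_{c=1}^{C} f_c \sum_{k=0}^{N}
  \int_{k}^{k+1} P(t) \prod_{i=1}^{I} P(x_{ij} \mid t)\,dt,
\qquad
P(x_{ij} \mid t) =
\begin{cases}
\mathcal{N}(x_{ij};\, g_i(t), \sigma_i) & \text{observed}\\
1/Z_i^{max} & \text{missing,}
\end{cases}
$$

so a missing biomarker contributes a flat density over its Z-score range:
it is marginalised out and cannot bias the estimated orderings, while the
subject's observed biomarkers still drive their subtype and stage.  The
package also implements the comparator strategies this device is
benchmarked against (subject deletion, column-mean imputation, two
K-nearest-neighbour imputation variants), a synthetic-data generator with
known ground truth, the evaluation metrics (Kendall sequence similarity,
subtyping accuracy, staging error, longitudinal-consistency rules,
modality ablation), and a control-referenced covariate-correction
pipeline for turning raw biomarker tables into SuStaIn-ready Z-scores.

Intended users: researchers in disease-progression modelling and
biostatistics who want event-sequence subtyping on incomplete multimodal
cohorts, or who want to benchmark missing-data handling for such models.

## Worked example

Simulate a 2-subtype cohort of 300 subjects over 5 biomarkers, delete
40% of the cells at random, and refit from the incomplete matrix (about
half a minute on one CPU):

```r
library(mdsustain)
set.seed(1)

truth <- simulateModel(C = 2, I = 5, levels = c(1, 2, 3), zMax = 5)
fractions(truth)
#> [1] 0.6 0.4

sim  <- simulateSubjects(truth, J = 300)
data <- injectMissingness(sim$data, round(0.4 * length(sim$data)))
sum(is.na(data))
#> [1] 600

fits <- fitSustain(data, modelConfig(truth), cMax = 2,
                   opts = sustainOptions(nStartpoints = 10, nMCMC = 5000),
                   missingMode = "uniform")
vapply(fits, logLik, numeric(1))
#> [1] -2627.412 -2590.094

post <- subjectPosteriors(data, mlModel(fits[[2]]), "uniform")
m    <- matchClusters(mlSubtype(post), sim$subtype, 2)
subtypeAccuracy(mlSubtype(post), sim$subtype, m, estStage = mlStage(post))
#> [1] 72.01493
vapply(1:2, function(c)
  sequenceSimilarity(sequences(mlModel(fits[[2]]))[c, ],
                     sequences(truth)[m[c], ]), numeric(1))
#> [1] 0.9619048 0.8476190
stagingError(mlStage(post), sim$stage)[, c("mean", "sd")]
#>       mean       sd
#> 1 1.786667 1.741051
sum(normalAppearing(post))
#> [1] 32
```

Despite 40% of all measurements being absent, the two-subtype model is
preferred by log likelihood, the recovered event orderings agree with
the generating ones at Kendall similarity 0.96 and 0.85, 72% of
subtypable subjects land in their generating cluster, and the average
staging error is under two of the 16 stages.  The 32 "normal appearing"
subjects sit at ML stage 0 (no detectable abnormality) and are excluded
from subtype accuracy.  `positionalVariance(fits[[2]])` gives the
per-subtype event-by-position frequency matrices behind
positional-variance heatmaps, and `credibleSets(post)` the per-subject
95% credible sets over (subtype, stage).

A command-line interface wrapping the same functions ships in
`exec/mdsustain` (subcommands `simulate`, `preprocess`, `fit`, `assign`,
`evaluate`, `benchmark`).

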