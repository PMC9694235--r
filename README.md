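# zoomnn

Backpropagation-free deep learning for resting-state fMRI region-of-interest
(ROI) classification, built from **zoom-in learning units (ZLUs)** stacked
into a **zoom-in neural network (ZNN)** over a neuro-fuzzy base learner
(**NEWFM**, a neural network with weighted fuzzy membership functions). The
package implements the full analysis protocol around the classifier — Haar
wavelet and graph-theoretic feature extraction from atlas-ROI time series,
per-ROI feature selection, discriminative-region selection, and hold-out
evaluation of the three one-vs-rest disease assessments (AD vs rest, NC vs
rest, MCI vs rest) — together with a synthetic cohort generator so the whole
pipeline runs and is testable without access-restricted imaging data.

## Who this is for

Researchers studying classifier architectures for functional neuroimaging
(rs-fMRI, AAL-90 atlas, subject classes AD / MCI / NC) who want a
reproducible, inspectable implementation of the feedforward zoom-in
architecture, and methodologists interested in backprop-free layerwise
training schemes.

## The model

**NEWFM.** For each feature *i* and class *c*, a bank of *m* triangular
membership functions with centers `c_ij` and weights `w_ij ∈ [0, 1]` defines
the bounded sum of weighted fuzzy memberships

```
b_ic(x) = min(1, Σ_j w_ij · μ_ij(x)),
```

The class score of an instance is `S_c = Σ_i b_ic(x_i)` over the selected
features; classification is `argmax_c S_c`, and the Takagi–Sugeno
defuzzified output (TSD) is the normalized contrast
`T = (S_1 − S_0) / (S_1 + S_0)` mapped to `[0, 1]`. Training is online and
gradient-free: the membership-maximal function of the true class pulls its
center toward the observation and gains weight proportionally
(`w ← w + δ(1 − w)`), the opposing winner decays (`w ← w − δw`). Built-in
feature selection ranks features by the non-overlap area
`∫ |b_1(x) − b_0(x)| dx` between the class curves.

**ZLU.** A standard NEWFM is trained, its errors split the training set into
misclassified (MI) and correctly classified (CCI) instances, and two further
NEWFMs are trained: a *subpattern* learner on the MIs (recovering patterns
the standard fit overlooked) and a *refined* learner on the CCIs. At test
time only these two are consulted; each ZLU emits a TSD pair `(t_m, t_c)`.

**ZNN.** Input features are split into contiguous blocks, one per
first-layer ZLU; each layer's concatenated TSD pairs are re-split to feed
the next layer; a final output NEWFM classifies the last TSD vector. There
is no backpropagation anywhere — each layer trains once, feedforward.

**Features per ROI (42).** 32 orthonormal Haar wavelet coefficients of the
first 128 timepoints (level-3 details d3 ×16, level-4 details d4 ×8,
level-4 approximation a4 ×8) plus 10 graph measures of the proportionally
thresholded absolute-correlation ROI graph: degree, node strength,
diversity coefficient, betweenness, k-coreness, subgraph, eigenvector and
PageRank centralities, and the graph-level assortativity and small-worldness
σ = (C/C_rand)/(L/L_rand).

## Worked example

```r
library(zoomnn)

# a small synthetic cohort: 30 ROIs, 5 informative, class-dependent
# low-frequency power and within-block connectivity
spec <- cohort_spec(
  n_per_class = c(AD = 20, MCI = 10, NC = 10), n_rois = 30,
  informative_rois = 1:5, spectral_effect = 3, connectivity_effect = 0.5,
  spectral_profile = c(AD = 1, MCI = 0, NC = 0),
  connectivity_profile = c(AD = 1, MCI = 0, NC = 0), seed = 1)
cohort <- simulate_cohort(spec)
features <- extract_features(cohort, seed = 2)

res <- run_assessment(cohort, "A-NM", layers = c(8, 4),
                      n_train_per_class = 6, n_rois = 8, n_keep = 10,
                      folds = 4, seed = 3, features = features)
res
#> ZNN assessment A-NM: ZLU layers [8, 4], 8 ROIs
#>   layer train     test
#>   zlu_1   100 86.36364
#>   zlu_2   100 90.90909
#>  output   100 90.90909

head(res$ranking$roi, 5)   # the 5 planted ROIs occupy the top ranks
#> [1] "ROI_002" "ROI_003" "ROI_004" "ROI_005" "ROI_001"
```

The report lists one train/test accuracy pair per ZLU layer plus the output
layer (in percent); the layerwise profile shows discrimination accumulating
as TSD pairs stack. `autoplot(res)` draws it; `glance(res)` and
`tidy(res)` give broom-style summaries. Fitted models serialize to
versioned JSON via `write_model()` / `read_model()`.

A thin command-line interface mirrors the stages
(`exec/zoomnn simulate | extract | rank | train | evaluate | report`), each
re-runnable from its upstream artifacts.

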