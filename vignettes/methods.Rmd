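---
title: "Missing-value substitutes for GC-MS metabolomics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-value substitutes for GC-MS metabolomics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamiss)
```

## The problem

GC-MS metabolomics feature tables routinely arrive with 10--20% of their
cells empty: peaks fall below detection, deconvolution fails, or signals are
lost in background. Most multivariate methods demand a complete matrix, so a
substitute must be chosen, and that choice is often made silently (mean
substitution being the unexamined default). `metamiss` implements five
substitutes -- zero, mean, median, feature-wise k-nearest-neighbour (kNN)
and iterative random-forest (RF) imputation -- together with the full
downstream read-out needed to judge them: autoscaling, cross-validated PCA
scree analysis, Ward-linkage clustering with a purity score, and
bootstrap-validated PC-LDA / PLS-DA classification. A synthetic-data
generator supplies tables with known ground truth so the imputation error
(NRMSE) is measurable, which real studies cannot offer.

## The five substitutes

**Zero / mean / median** replace every hole in a metabolite column with a
constant: 0, the observed-value mean, or the observed-value median. All
three necessarily erase any sample-specific information in the imputed
cells; they differ only in where the constant sits relative to the bulk of
the distribution.

**kNN (features as neighbours).** For each metabolite with holes, the
Euclidean distance to every other metabolite is computed as a *partial*
distance -- the root mean square difference over the samples where both are
observed -- so candidates with their own holes still receive a distance.
The k (default 10) nearest metabolites form the neighbour set; a hole at
sample *s* is filled with the unweighted mean of the neighbours observed at
*s*, falling back to the metabolite's own observed mean when no neighbour is
observed there (counted in `fallback_count`). Equidistant neighbours are
broken deterministically by lowest feature index. Inverse-distance weighting
exists behind `weighted = TRUE` but is off by default: the unweighted
average is the behaviour of the classical expression-data implementation
this follows.

**RF (iterative forests).** The missForest-style scheme: initialize holes
with feature means; visit features in order of increasing missingness; for
each, fit a regression random forest of that feature on all others using the
rows where it is observed and overwrite its holes with forest predictions.
After every full sweep the relative change
$\Delta = \sum (X_\text{new} - X_\text{old})^2 / \sum X_\text{new}^2$
is recorded; iteration stops when $\Delta$ rises (returning the matrix from
the sweep before the rise) or at `max_iter` (default 10). The forest is
written in C++ (CART trees, bootstrap resampling, `mtry = floor(sqrt(p-1))`
features per split, minimum node size 5, 100 trees), matching the defaults
of the package that popularized the method. Two published RF imputation
schemes exist -- proximity-matrix averaging and iterative regression; the
iterative-regression scheme is implemented because it is the algorithm of
the reference implementation. The published stopping phrase about "both
differences" concerns mixed continuous/categorical data; with purely
continuous intensity data a single $\Delta$ criterion applies.

Imputation operates on the internal-standard-normalized, unscaled intensity
scale; autoscaling comes strictly afterwards.

## Imputation error

`nrmse()` scores a completed table against the retained ground truth:
$\sqrt{\operatorname{mean}[(\hat x - x)^2] / \operatorname{var}_\text{pop}(x)}$
over the masked cells only, with the population variance (n denominator) of
the true masked values. The normalization makes two anchors exact: perfect
imputation scores 0, and filling every hole with the mean of the true masked
values scores exactly 1.

## Downstream evaluation

**Autoscaling** (`autoscale()`) centers each feature and divides by its
*sample* standard deviation (n−1 denominator -- the convention is stated
once here and used everywhere; the source material is silent on it). Holes
must already be filled: the function refuses incomplete input. Held-out data
are always scaled with training-fold parameters (`apply_autoscale()`);
inside resampling loops a tolerant variant maps bootstrap-degenerate
constant columns to 0 instead of erroring.

**Cross-validated scree analysis** (`cv_scree()`): 10-fold cross-validation
repeated 100 times (defaults). Per fold, PCA is fitted on the training folds
and the cumulative total explained variance (TEV) per component recorded;
held-out rows, scaled with training parameters and projected on training
loadings, give $Q^2 = 1 - \text{PRESS}/\text{TSS}$ per component count (the
source never writes the formula; this is the standard choice). The
"minimum number of components" at the TEV threshold (default 80%) is
computed per repetition from the across-folds mean curve; a per-fold
variant is recorded alongside because the original figure does not say
which summary its arrows use. Folds are seeded, shuffled,
non-stratified, and as equal as divisibility allows.

**Ward HCA + purity** (`ward_hca()`, `cluster_purity()`): Euclidean
distances with the squared-Euclidean "ward.D2" update -- the era of the
original toolchain leaves the Ward variant ambiguous, so the choice is fixed
here and pinned by tests (two singletons merge at their plain Euclidean
distance). Purity cuts the tree into k clusters (default: the number of
classes) and reports the size-weighted fraction of samples belonging to each
cluster's majority class.

**PC-LDA** projects autoscaled data onto principal components (sidestepping
the collinearity that plain LDA cannot handle -- feasibility is the sample
budget check `lda_feasible()`, $(N_s - N_g - 1) > N_v$) and runs Fisher LDA
with pooled within-class covariance on the scores. Priors follow training
class frequencies; a ridge of $10^{-8} \times \operatorname{tr}(S_W)$ keeps
the pooled covariance invertible -- a numerical safeguard, not part of the
source method. **PLS-DA** regresses the centered one-hot class matrix on
autoscaled predictors via classical NIPALS PLS2 (X- and Y-deflation,
convergence tolerance $10^{-10}$, at most 500 inner iterations) and assigns
test samples to the class with the largest predicted dummy entry, exact ties
going to the earliest class in `class_order`. With three *collinear* class
centroids a single latent variable cannot recover the middle class by argmax
(its dummy response is non-monotone in the score) -- an intrinsic property
of linear dummy regression worth knowing before reading accuracy curves.

**Bootstrap validation** (`bootstrap_evaluate()`): 100 resamples of n
samples with replacement form training sets (on average 63.2% distinct
samples); the out-of-bag remainder (~36.8%) is the test set. Resamples
missing a class, or with fewer than two training samples of some class, are
redrawn and counted. Accuracy is recorded for every component count
1..`max_components`, and the reported component count is the *first
effective maximum* of the mean accuracy curve: the smallest count that no
larger count beats by more than `selection_tol` (default 0.5 accuracy
points). Two literal formalizations of "first local maximum" were
implemented and rejected on evidence. A strict-on-both-sides rule
degenerates on saturation plateaus (..., 99.9, 100, 100, ... has no strict
maximum). A strict-left/tied-right rule is Monte-Carlo fragile: at 50--100
resamples, a 0.02-point ripple in a rising curve creates a spurious early
"peak", selecting 2 components at 68% accuracy on a curve that reaches 86%.
The tolerance rule reads rising curves (selects where the rise flattens
within tolerance), peaked curves (selects the first near-peak count),
plateaus (their first point) and flat curves (1 component) the way the
original figure's arrows were evidently read by eye. A completely flat
curve still selects 1.
Imputation is performed once on the full table before resampling, mirroring
the original workflow; per-resample imputation is available via
`compare_methods`'s building blocks for leakage-sensitive use but is not
the default.

## The synthetic world

`generate_complete()` emulates the structure described for the study the
pipeline reproduces: a ~52-metabolite GC-MS table over three oxygen
conditions with ~15% missing cells. Its frozen defaults state that world:

* **Intensities** are per-feature log-normal, $x = e^{\mu_j + \sigma_j z}$,
  with shapes $\sigma_j \sim U(0.1, 1.2)$. At class sizes of ~30 this spans
  sample skewness from near 0 to beyond 3--4, matching the published
  per-class skewness table (range roughly −2.7 to +4.2); 15% of features
  are reflected to produce the negatively skewed minority.
* **Co-regulation**: 5 blocks of 10 features share a latent factor
  (pairwise latent correlation 0.85), a common intensity scale (log-mean
  jitter 0.05) and a common class response. This encodes what co-regulated
  and chemically related features look like in real GC-MS tables -- the
  study's own table lists several isomer/derivative features of the same
  sugars, which track each other closely. Dense correlation is also the
  regime in which neighbour-based imputation is meaningful at all: kNN with
  k = 10 needs neighbourhoods of comparable scale to average.
* **Class structure**: 80% of features respond to class, with log-mean
  shifts of scale 1.2 (blocks respond as a unit). This was calibrated once
  against the published operating point -- best-method classification in the
  mid-90s, all methods within the published 78--98% band -- and then frozen.
* **Missingness** (`apply_missingness()`): exactly
  `round(0.15 * n_cells)` cells are deleted by weighted sampling without
  replacement, so the realized fraction is reproducible. `MCAR` uses uniform
  weights; `LOD` uses rank-based weights $(1 - (r - 0.5)/n)^3$ that
  concentrate deletion on low intensities without a hard threshold, keeping
  the count controllable; the default `MIXED` draws 70% of deletions from
  the LOD weights and the rest uniformly. The LOD-dominated default follows
  the description of GC-MS missingness as driven largely by low signal
  intensity. A draw that would empty a feature column is rejected and
  redrawn, so downstream imputer preconditions always hold.

### What a green test does and does not establish

The generator reproduces marginal skewness, block correlation, class
separability and missingness fraction. It does **not** model batch drift,
retention-time misalignment, derivatization chemistry, heteroscedastic
technical noise, or the particular per-metabolite detection limits of a real
instrument. Green ordering tests therefore establish that the pipeline
*can* discriminate imputation quality in a world with the stated structure
-- not that the published accuracy figures are recovered (the study's
dataset was never deposited, so they are unreproducible in principle).

### Where the stated world disagrees with the published pattern

Two pieces of the published method ordering do not emerge in this world,
and the corresponding acceptance assertions are deliberately left failing
rather than weakened:

* **Zero vs mean.** In the published comparison, zero substitution
  (~92%) far outperformed mean substitution (~78%). Here mean substitution
  beats zero by 1.5--3 accuracy points under every mechanism tried. The
  analysis: a zero sits several standard deviations below the bulk of a
  mildly skewed feature, inflating its post-imputation variance and
  crushing its autoscaled class signal, while the observed-value mean is at
  most a few tenths of a standard deviation from the bulk. Zeros can only
  win when missingness is concentrated at *low, low-variance* intensities
  hard enough that zero approximates the censored truth -- evidently the
  situation in the real data, and stronger than the rank-based LOD model
  produces. The magnitude of the published mean-substitution collapse
  (~14 points) is not reproduced either; only its direction is.
* **kNN vs mean NRMSE.** The world-level difference is 0.00 ± 0.07 -- a
  knife-edge decided by seed. Feature-wise kNN averages raw neighbour
  intensities, so its error is dominated by the few features without
  same-scale neighbours; the mean-constant baseline makes no scale errors.

Everything else in the published ordering replicates robustly: RF best in
both error and classification; kNN at or above the single-value substitutes
in classification; median at or above mean; and mean never the best input.
The scree-plot observation that median imputation retains more PC1 variance
than mean imputation replicates under the LOD-containing mechanisms (and
*reverses* under pure MCAR, where the mean constant is the MSE-optimal one
-- the same mechanism story as above).

## Numerical choices, degenerate inputs, tie-breaks

* Sample sd (n−1) throughout; skewness defaults to the population-moment
  estimator $g_1 = m_3 / m_2^{3/2}$ with the adjusted Fisher--Pearson
  variant behind a switch (the published table's estimator is
  unidentifiable without the raw data); kurtosis is reported as excess.
* "Detected in QC" means non-missing regardless of magnitude; the QC CV
  filter uses observed QC values only and needs at least two of them.
* kNN neighbour ties break to the lowest feature index; PLS-DA argmax ties
  break to the earliest class in `class_order`; both deterministic.
* All randomness flows from explicit seeds through a private RNG scope that
  restores the caller's `.Random.seed`; a master pipeline seed is expanded
  into named per-stage seeds so stages can be re-run in isolation.
* Bootstrap component counts are capped at the resample's numeric rank;
  accuracies beyond it are `NA` and excluded from the mean curve.

## Known limitations

* The acceptance comparison uses PLS-DA rates (PC-LDA behaves
  indistinguishably on these fixtures but doubles the cost).
* kNN distances are computed on raw normalized intensities, as in the
  reference implementation; no option to compute them on scaled data is
  offered, because the original workflow imputes before autoscaling.
* The forest uses midpoint splits on sorted unique values and R's RNG;
  results are reproducible across platforms but not bit-identical to any
  other forest implementation.
* QC samples, when generated, are mean-profile injections with 5% log-normal
  noise -- sufficient for exercising the detection/CV filters, far simpler
  than real pooled-QC behaviour across batches.
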