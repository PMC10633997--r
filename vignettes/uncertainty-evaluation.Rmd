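---
title: "Evaluating uncertainty estimators for molecular property regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating uncertainty estimators for molecular property regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molUQ)
```

## The problem

QSAR-style property models predict a real-valued molecular property (a
solubility, a redox potential) from precomputed numeric descriptors. For
screening and experimental design the point prediction is not enough: each
prediction needs an uncertainty, and that uncertainty has to remain
informative when the query molecule is structurally unlike anything in the
training set. molUQ implements a family of per-molecule uncertainty
estimators under one contract, four complementary metrics that probe
different senses of "good uncertainty", and a single-iteration pool-based
active-learning experiment that measures whether an estimator's uncertainty
actually helps a model generalize faster to a held-out structural region.

## Estimators

Every estimator returns a `UQEstimate`: a predicted mean, a nonnegative
`sigma` per molecule, and a `calibrated` flag.

* **Quantile GBM** (`fitQuantileGbm` + `gbmQuantileUQ`): gradient-boosted
  trees trained with the pinball loss at the 10% and 90% quantiles;
  `sigma = (P90 - P10)/2`. Crossed quantiles are clipped to zero with a
  warning.
* **Deep ensemble** (`ensembleUQ`): M = 5 feedforward networks differing
  only in seed; `sigma` is the population (divide-by-M) standard deviation
  of member predictions.
* **Monte Carlo dropout** (`mcdoUQ`): T = 30 stochastic forward passes with
  dropout active at inference; seeded, hence reproducible.
* **Mean-variance estimation** (`trainRegressor(head = "mve")` + `mveUQ`):
  the network outputs `(mu(x), sigma2(x))` and is trained with the Gaussian
  negative log-likelihood; `sigma = sqrt(sigma2)`.
* **Evidential regression** (`head = "evidential"` + `evidentialUQ`): the
  network outputs the four parameters `(gamma, upsilon, alpha, beta)` of a
  Normal-Inverse-Gamma distribution over `(mu, sigma2)`. The moments
  `E[sigma2] = beta/(alpha - 1)` (aleatoric) and
  `Var[mu] = beta/(upsilon (alpha - 1))` (epistemic) separate noise from
  model uncertainty; the reported component defaults to epistemic and is
  configurable. Training minimises the marginal Student-t negative
  log-likelihood plus an evidence regularizer
  `lambda |y - gamma| (2 upsilon + alpha)` with `lambda = 0.01`.
* **Union** (`unionUQ`): quantile GBMs fitted on the network's last hidden
  layer; the network keeps the mean, the trees supply the interval.
* **kNN density** (`knnDensityUQ`): mean cosine distance to the 3 nearest
  training molecules, in descriptor space ("fp") or embedding space
  ("eb"). Purely dataset-dependent and only a relative score, so
  `calibrated = FALSE`.
* **Consensus** (`consensusUQ`): elementwise mean of the means and sigmas
  of several calibrated estimates (used with GBM, MC dropout and MVE).

### Uncertainty units

Ensemble, dropout, MVE and evidential uncertainties are reported as
standard deviations, not variances. The calibration metric below squares
`sigma` inside its root-mean-variance, which presumes an error-scale
quantity; rank-based metrics are unaffected by the choice (a property the
test suite checks explicitly).

## Metrics

* **ENCE** (`ence`): molecules are sorted by `sigma` and split into 10
  equal-count bins; per bin the root mean variance
  `RMV = sqrt(mean(sigma^2))` is compared with the empirical
  `RMSE`, and `ENCE = mean(|RMV - RMSE| / RMV)`. Equal-count binning is
  used because equal-width bins can be empty or have `RMV = 0`, which the
  metric cannot tolerate; bin sizes differ by at most one even under ties
  (rank binning with a stable tie-break). For uncalibrated density
  estimates ENCE is reported as not applicable (NA).
* **Error correlation** (`rhoError`): Spearman correlation between
  per-molecule absolute error and `sigma`. Absolute (not squared) error is
  used; the two give identical ranks.
* **OOD correlation** (`rhoOod`): Spearman correlation between `sigma` and
  `1 - similarity` over a pool whose maximum-similarity-to-training scores
  were downsampled to be uniform on [0,1] (`uniformSimilaritySample`, 10
  strata, counts equal within one). The sign convention makes "dissimilar
  molecules receive higher uncertainty" positive, so larger is better for
  every correlation column in a report.
* **Delta-error correlation** (`runDeltaErrorStudy` + `rhoDeltaError`):
  PCA is run on the z-scored descriptors of the full dataset
  (`pcaTopBins`); each of the top components is cut into 5 equal-count
  percentile bins; each bin in turn is removed from the training and
  validation sets, the model is retrained, and on the removed bin's test
  molecules the change in RMSE is paired with the change in mean
  uncertainty. The Spearman correlation across the (component, bin)
  scenarios is the metric. The mean is used to aggregate `sigma` over the
  bin, mirroring the RMSE-style aggregation of the error.

An alternative grouping for the leave-out construction is provided by
`butinaClusters`, a deterministic sphere-exclusion clustering (centroid =
unassigned item with most unassigned neighbours above the similarity
threshold, lowest index on ties), and `groupMeanDistance` reports
within/between group mean distances on the induced scale
`2 (1 - similarity)` in [0, 2].

## The active-learning experiment

`runAlExperiment` performs one acquisition round per repetition: a seeded
initial training sample (for the leave-bin-out scenario the removed bin is
excluded from the initial sample but remains in the candidate pool and the
test set), a model fit, pool-uncertainty scoring, batch selection,
retraining, and evaluation of the test RMSE on the removed (OOD) bin, the
remaining (ID) bins, and the whole test set. Selection is linear in the
uncertainty - a molecule with twice the uncertainty is twice as likely to
be drawn at each without-replacement draw (sequential draw + renormalize,
which is what `sample(prob = )` implements). Baselines: uniform random,
diversity (weights proportional to a pool member's mean pairwise distance
to the rest of the pool, embedding space), and an `ood_only` oracle that
samples only removed-bin molecules (an upper reference, impossible in
practice; a batch larger than the bin pool is capped with a warning).
Pool members with zero uncertainty get zero selection probability; users
wanting an exploration floor can add a constant to `sigma` before calling
`selectBatch`.

Every sampler's arm shares the repetition's initial training sample with
the random arm, so `improvementPct` (mean of
`100 (rmse_random - rmse_al)/rmse_random`) and `pairedOneSidedT` (one-sided
alternative: AL beats random) operate on genuinely paired repetitions.
Zero-variance differences yield a flagged degenerate result rather than a
p-value. The full grid of the study design - initial fractions
{5, 10, 20, 40}%, batch sizes {25, 50, 100, 250, 500, 1000}, 15
leave-bin-out scenarios - enumerates to 24 combinations and 360
experiments (`enumerateAlGrid`), run at 30 repetitions in the full design
and reducible for desk-scale work.

## The synthetic data generator

`generateDataset` emulates the features of curated descriptor datasets
that the evaluation depends on, with known ground truth:

* **Clustered descriptors.** Molecules fall into `nClusters` Gaussian
  clusters whose centres share a dominant direction plus per-cluster
  offsets three times the within-cluster spread. The shared direction
  mirrors the fact that real descriptor and fingerprint vectors occupy a
  cone (nonnegative, correlated features) rather than the whole sphere; it
  is also what allows maximum-similarity-to-training to sweep the full
  [0,1] range for the OOD pool. PCA percentile bins consequently
  correspond to structural regions, and `scenarioPurity` reports how
  cleanly each (component, bin) scenario isolates one cluster.
* **Two representation blocks.** Embeddings are a fixed seeded linear
  projection of the descriptors to `nEmbedding` dimensions plus 5%
  relative noise - correlated with, but not identical to, descriptor
  geometry, mirroring the descriptor-versus-embedding duality of the
  density estimators.
* **A smooth nonlinear teacher.** `y = f(X) + eps`, where f is a fixed
  seeded two-layer tanh network whose first layer is sparse (each hidden
  unit reads two descriptors, scaled for unit pre-activations).
  Sparseness gives the low-order feature interactions typical of
  engineered descriptors; a dense random first layer at this input scale
  saturates into a step-like function that no desk-scale model family can
  approach its noise floor on, which would leave every calibration signal
  buried under model error.
* **Known heteroscedastic noise.** `eps ~ N(0, sigmaTrue(x)^2)` with
  `sigmaTrue(x) = noiseBase + noiseHetero * g(x)`, `g` a logistic ramp
  along a fixed direction with values in [0,1]. Defaults
  `noiseBase = 0.3`, `noiseHetero = 0.6` put the noise floor at roughly
  20-35% of the target spread, the regime of experimental solubility
  data; the heteroscedastic form itself is an assumption, since the noise
  structure of real measurements is not characterised.
* **A graded OOD pool.** `makeOodPool` displaces cluster centres along the
  negative of the shared direction by a level drawn uniformly from
  `levelRange`; level 0 is in-distribution, level 1 reaches past the
  antipodal region (default `oodDisplacement = 28`, chosen so the minimum
  reachable similarity is safely below 0.1 and every similarity stratum of
  the uniform downsampling is populated). Targets still come from the
  same teacher, so pool molecules can be labelled and consumed by active
  learning.

All randomness flows through named per-purpose seed streams derived from
the configuration seed, so paired experimental arms share exactly the
streams they must share (for example, the AL and random arms of a
repetition share the initial-sample stream) and every output is
bit-reproducible.

### What the generator does not emulate

Real descriptor blocks are higher-dimensional (hundreds of features),
partly discrete, and collinear; real structure-activity landscapes have
activity cliffs that no smooth teacher reproduces; and assay noise is not
Gaussian in general. A passing synthetic suite shows the machinery is
correct and that each estimator responds to the signals it is designed to
see; it does not certify performance levels on any real dataset.

## Model-fitting choices

The feedforward regressor is a compact dense-network engine written for
this package (tanh hidden layers, inverted dropout, Adam with optional
per-epoch learning-rate decay, early stopping on a 10% seeded validation
split, analytic gradients for all three heads). Defaults
(`hiddenSizes = c(128, 64)`, dropout 0.2, patience 20) are sized for a few
thousand molecules with tens of descriptors. After the stochastic phase an
optional full-batch L-BFGS polish (`polishIters`) refines the weights when
dropout is off; the polished weights are kept only if the validation loss
does not worsen. Polishing matters for near-noiseless targets, where
minibatch noise otherwise sets the error floor. Head positivity uses
softplus with a `1e-6` floor, and `alpha = 1 + softplus` keeps the
evidential moments finite.

Quantile-GBM defaults (100 rounds, depth 2, learning rate 0.1,
`min_child_weight = 40`, `subsample = 0.6`) are deliberately much more
conservative than a typical squared-error configuration: the pinball loss
overfits quickly, and an overfit quantile model produces collapsed
intervals - at desk scale a 500-tree depth-6 configuration yields held-out
[P10, P90] coverage near 64% instead of the nominal 80%. Mean fits pass
stronger settings explicitly.

## Numerical and procedural choices

* Equal-count binning everywhere a quantity is split into bins (ENCE,
  PCA percentiles), implemented as rank binning with a stable first-index
  tie-break: sizes differ by at most one under arbitrary ties.
* Spearman correlation is average-rank Pearson (ties get mean ranks);
  constant vectors are an error rather than an NA.
* `rhoOod` is oriented as Spearman(`sigma`, `1 - similarity`): the
  sign convention is fixed so that good estimators score positive.
* PCA for the bin construction is fitted on the z-scored full dataset,
  because the bins partition the full dataset, not the training split.
* Degenerate inputs fail loudly: zero vectors in cosine similarity,
  RMV = 0 bins, all-zero selection weights, empty strata in the uniform
  downsample (the error names the offending strata).
* The evidential reported component defaults to epistemic (`Var[mu]`),
  the component that should rise out of distribution; which component the
  study design intends is otherwise unspecified.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full pipeline at
reduced sizes chosen to keep everything reproducible on a single CPU:
6,250 molecules for calibration and coverage studies, 2,500 for the
leave-bin-out and active-learning experiments, 500-molecule uniform OOD
pools, one PCA component by 5 bins for the delta-error study, and 10
paired repetitions for the AL experiment. The active-learning scenario
used in summaries is the most cluster-coherent edge bin (highest
`scenarioPurity` among bins 1 and 5): an edge bin requires genuine
extrapolation, whereas a middle bin can be interpolated from its flanking
regions, which dilutes what the scenario is constructed to measure.

## Known limitations

* Density uncertainties are relative scores; they cannot be calibrated
  into expected-error units without a mapping that this package (like the
  study design it implements) does not attempt.
* The evidential head is the hardest to optimise; on very small samples
  its uncertainty ordering is reliable but its absolute scale is not.
* A single acquisition round is implemented by design; multi-round
  active learning would need model-state carry-over that the runner does
  not provide.
* `runUqEvaluation` builds its OOD pool from the synthetic generator's
  configuration; for file-loaded datasets the pool-based metric requires
  a user-supplied pool.
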