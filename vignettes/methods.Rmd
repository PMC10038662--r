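---
title: "Modeling odd-one-out similarity judgments and linking them to brain data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling odd-one-out similarity judgments and linking them to brain data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(oddoneout)
```

## The triplet odd-one-out task and its choice model

In the triplet odd-one-out task, a participant sees three objects and picks
the one that is most dissimilar.  The remaining pair is the implied most
similar pair *in the context of the third object*.  With broad object
coverage, aggregated choices yield a context-independent estimate of
perceived similarity, and restricting triples to a category yields
context-dependent (within-category) similarity.

The sparse positive similarity embedding (SPoSE) model represents each
object $i$ as a non-negative vector $x_i \in \mathbb{R}_{\ge 0}^d$.  For a
triple $\{i, j, k\}$ the three pairwise dot products
$s_{ij} = x_i \cdot x_j$ enter a softmax (no temperature):

$$P(k \text{ is the odd one out}) =
  \frac{e^{s_{ij}}}{e^{s_{ij}} + e^{s_{ik}} + e^{s_{jk}}}.$$

The training objective is the cross-entropy of the observed choices plus a
sparsity-inducing L1 penalty,

$$\mathcal{L}(W) = -\frac{1}{T}\sum_t \log P(\text{choice}_t)
  + \frac{\lambda}{n} \sum_{i,d} |w_{id}|,$$

where $n$ is the number of objects.  The per-object normalization of the
penalty is a package choice (the objective's description leaves it open);
it keeps the meaning of $\lambda$ roughly stable across object-set sizes.
Non-negativity plus L1 produces sparse, interpretable dimensions.

## Optimization and its tunable parameters

`train_spose()` minimizes the objective by minibatch Adam (step 0.001,
decay rates 0.9/0.999, epsilon $10^{-8}$ — the usual defaults), projecting
the weights onto the non-negative orthant after every update.  The
relevant `spose_config()` parameters:

* `init_dims = 90` — the embedding starts from 90 dimensions drawn
  uniformly on $[0, 1)$; superfluous dimensions are driven to zero by the
  penalty and removed afterwards.
* `batch_size = 100` triplets per gradient step.
* `lambda` — the L1 weight; select it with `select_lambda()` by k-fold
  cross-validation on held-out cross-entropy.  `0.00385` is the right
  order of magnitude for datasets with thousands of objects and millions
  of trials; desk-scale synthetic datasets need a larger value (the grid
  and folds are up to the user; this vignette's experiments use the
  one-standard-error rule, see below).
* `prune_threshold = 0.1` — after training, a dimension is removed when
  *all* of its weights are below 0.1; retained dimensions are sorted by
  descending weight sum.
* `val_fraction = 0.1`, `val_tol = 1e-4`, `patience = 20` — a held-out
  slice of the training trials monitors cross-entropy; training stops
  after `patience` epochs without an improvement of at least `val_tol`.
  The patience default is deliberately generous: validation cross-entropy
  plateaus well before the L1 term finishes shrinking redundant
  dimensions, and stopping at the plateau (e.g. after 10 stalled epochs)
  leaves many near-duplicate dimensions above the pruning threshold.
  With patience 20 the desk-scale recovery experiment below prunes to the
  true dimensionality; with patience 10 it retains an order of magnitude
  too many dimensions.

Minibatch order is reshuffled every epoch (Mersenne Twister, seeded), the
90–10 train/test split is uniform over trials without pair stratification,
and every function that touches randomness takes an explicit `seed`, so
all results are bit-reproducible.

Because the optimization is stochastic, `train_spose_restarts()` refits
the model from many random initializations (72 is the convention for
production embeddings) and keeps the restart with the highest
reproducibility index: for each dimension, the best-matching dimension in
every other restart is found by Pearson correlation, the correlations are
Fisher-z averaged and back-transformed to r (back-transforming is a
package choice; it is monotone, so the selection is unaffected).
Zero-variance dimensions contribute r = 0 with a warning.

## Cross-validated choice of lambda

`select_lambda()` scores each grid value by mean held-out cross-entropy.
Two decision rules are available: `"min"` (the default — the CE
minimizer, ties toward the smaller value) and `"1se"`, the familiar
one-standard-error convention that picks the sparsest value within one
standard error of the minimum.  For dimensionality-recovery purposes the
`"1se"` rule is preferable: around the CE minimum the held-out fit is
flat, while the sparser solution prunes redundant dimensions decisively.

## Noise ceilings

For repeated neuroimaging measurements, `neuro_noise_ceiling()` uses the
signal/noise variance decomposition: the noise variance is the pooled
(unweighted mean, repeats being balanced) per-image variance across
repeats; the signal variance is the variance of the image-wise means; and
the ceiling — the maximum fraction of variance any model could explain —
is

$$\mathrm{NC}(n) = \frac{\sigma^2_{\text{signal}}}
  {\sigma^2_{\text{signal}} + \sigma^2_{\text{noise}} / n},$$

where $n$ (`n_average`) is the number of repeats averaged downstream
(1 for single-trial use, 12 for a 12-repeat test set).  The variance of
the image means overestimates the signal variance by about
$\sigma^2_{\text{noise}}/R$ for $R$ repeats; `bias_correct = TRUE`
subtracts that term (floored at zero).  The default is `FALSE`, matching
the plain variance-of-means description; the bias-corrected mode recovers
the analytic ceiling to within ±0.02 on simulations with 5,000 images.

For repeated behavioral triplets, `behavioral_noise_ceiling()` averages
per-triplet choice consistency (modal choice count over repeats, in
percent).  Because the modal choice is estimated from the same sample, the
estimator is upwardly biased — the result carries that caveat in its
`"estimator"` attribute, and no corrected estimator is provided.

## Dimensionality versus dataset size

Embedding dimensionality grows with the number of trials but saturates.
`fit_exp_decay()` fits

$$\mathrm{dims}(x) = a + b e^{-c x}, \qquad c > 0,$$

to mean dimensionality over dataset sizes by Levenberg–Marquardt least
squares from several starting points ($a_0 \in \{y_\text{last},
y_\text{last} + (y_\text{last}-y_\text{first})/4\}$, $b_0 = y_\text{first}
- a_0$, $c_0 \in \{1, 5\}/\text{range}(x)$), keeping the converged fit
with the lowest residual sum of squares; $a$ is the asymptotic
dimensionality.  Near-constant responses make $b$ unidentifiable and
raise an error rather than returning a degenerate fit.

`bootstrap_asymptote()` quantifies uncertainty by resampling the
replicate dimensionalities per size (with replacement), refitting, and
taking the (2.5, 97.5) percentile interval of the asymptotes over 1000
draws.  Bootstrap refits are warm-started from the observed fit, which is
numerically identical to the full multi-start search on these curves and
an order of magnitude faster; draws whose refit fails are skipped (an
error is raised if more than 10% fail).  Note a genuine small-sample
caveat: with only 4 replicates per size, resampling underestimates the
variance of each mean by the factor $(R-1)/R = 3/4$, so the nominal 95%
percentile interval covers the true asymptote in only about 87–91% of
simulated curves.  This is inherent to the percentile bootstrap at this
replicate count, not an implementation artifact.

## Choice-probability similarity and RSA

`choice_prob_similarity()` converts an embedding into a behavioral
similarity matrix: $\mathrm{sim}(i, j)$ is the model probability that a
third object $k$ is the odd one out of $\{i, j, k\}$, averaged over all
other objects $k$ in the context.  Restricting `context` to one category
changes the third objects and therefore the similarities — within-category
structure that the full-context matrix dilutes.  Subsetting the
full-context matrix is *not* the same computation, and a test asserts the
difference.  Self-similarity is undefined in the task; the diagonal is
stored as 1 by convention and excluded from every statistic.

Dissimilarity is $1 - \mathrm{sim}$ (similarities are probabilities), the
strictly-lower-triangular part is vectorized in row-major order (fixed so
correlations are bit-reproducible), and representational similarity
between two matrices is the Pearson correlation of those vectors.
`bootstrap_object_rsa()` resamples *objects*, not cells — cells sharing an
object are dependent — and treats duplicate concepts (datasets often
include several images of one concept) as single resampling units,
keeping pairs between distinct duplicates and dropping exact self-pairs.
`improvement_test()` aggregates over datasets with a majority rule on
aligned bootstrap draws: a draw counts as an overall improvement only when
more than half the datasets improve (ties are non-improvements), and the
p-value is the fraction of non-improvement draws.

## Regression-based sensor-to-region fusion

`fit_fusion()` asks *when* the information carried by a region's response
is present in time-resolved sensor data: separately at every timepoint, an
ordinary least-squares model (with intercept — harmless when centered,
necessary otherwise) predicts the per-trial scalar region response from
the sensor pattern, trained with leave-one-session-out cross-validation
and scored by the Pearson correlation between predicted and true
responses on the held-out session.  Rank-deficient training (fewer rows
than sensors + 1) falls back to the minimum-norm solution with a logged
warning; folds with constant truth or prediction are recorded as missing
and excluded from means and resampling.  The across-fold mean is smoothed
by a centered moving average of 5 timepoints, truncated at the edges.

`supra_baseline_window()` operationalizes "when does the signal become
real": the threshold is the maximum smoothed correlation during the
pre-stimulus baseline, and the window is the longest contiguous run of
timepoints strictly above it (ties to the earliest run; an empty window is
legitimate).  `bootstrap_fusion_ci()` and `roi_contrast()` resample the
fold-wise statistics (the folds are the exchangeable unit, matching the
12-fold session scheme) with percentile 95% intervals; contrasts use
fold-paired differences.

A calibration caveat, documented deliberately: leave-one-session-out fold
statistics share training data and are therefore positively correlated
across folds.  Resampling them as if exchangeable underestimates the
variance of the fold mean by a roughly constant factor (≈1.5× in standard
deviation in our pure-noise simulations, stable across 6–24 sessions and
a range of trial counts), so the nominal 5% false-positive rate of the
95% band is closer to 15–30% under the null.  This is the well-known
absence of an unbiased variance estimator for cross-validation, not a
bug; onset *ordering* conclusions (which region becomes predictable
first) are driven by the supra-baseline rule and are robust to it.

## What the synthetic data emulate — and what they do not

The generators produce every input of the pipeline with known ground
truth:

* `make_ground_truth_embedding()` — non-negative weights, each entry zero
  with probability `sparsity`, non-zeros exponential with mean `scale`
  (right-skewed, like fitted SPoSE weight histograms).
* `sample_triplet_tasks()` — shuffled enumeration of all triples with
  cyclic refill, so pair coverage is near-uniform, exactly uniform when
  the trial count is a multiple of the number of triples; this mirrors
  designs that sample every similarity-matrix cell roughly equally often.
* `simulate_choices()` — the softmax model run forward.  The true
  generative noise process behind human choices is unknown; the
  self-consistent softmax forward model is an assumption, so
  recovery results speak to internal consistency, not to human data.
* `simulate_repeated_measures()` — Gaussian signal plus i.i.d. Gaussian
  repeat noise per channel-image cell.
* `simulate_fusion_data()` — one latent feature per region per trial; a
  fixed sensor loading of that feature switches on at the region's onset
  latency; noise standard deviations are `1/snr`; sessions are contiguous
  trial blocks.

Real data differ in ways these generators do not capture: participant
heterogeneity and response-time structure, non-uniform sampling designs,
temporally autocorrelated sensor noise, overlapping and graded latencies,
and session-level drifts.  Passing recovery tests therefore demonstrates
that the estimators invert their own generative assumptions at realistic
sizes — a necessary, not sufficient, condition for trusting them on real
data.

## Problem sizes used by the test and acceptance runs

The parameter-recovery experiment uses 50 objects, a 5-dimensional ground
truth with 60% sparsity, 50,000 triplets (90–10 split), lambda selected
by 2-fold cross-validation with the one-standard-error rule over
{0.01, 0.025, 0.05, 0.1}, and 10 replicate seeds.  Noise-ceiling
simulations use 5,000 images with 12 repeats.  Extrapolation uses the
14-size, 4-replicate design (100,000 to 1.4 million trials) with
replicate noise SD 2 and 1000 bootstrap draws; coverage is assessed over
100 simulated curves.  Fusion uses 360 trials, 16 sensors, 12 sessions,
51 timepoints from −100 to 400 ms, injected onsets at 100 and 180 ms,
snr 1, and 20 replicate simulations.  These sizes were chosen as the
smallest at which the estimators' asymptotic behavior is clearly
expressed.

## Known limitations

* The behavioral consistency ceiling is upwardly biased (sample-modal
  estimator); no correction is applied.
* Percentile bootstrap intervals undercover at 4 replicates per size
  (extrapolation) and under cross-validation dependence (fusion); see the
  sections above for magnitudes.
* `select_lambda()` refits the full model for every fold × grid cell;
  for large datasets choose a coarse grid first.
* The package consumes neural dissimilarity matrices and fusion
  containers; it does not preprocess raw recordings.  `fusion_dataset()`
  documents the expected layout and validates invariants for converted
  real data, including both reasonable conventions for matching trials
  across modalities (average region responses across subjects before
  trial matching, or match per subject and average afterwards) — the
  choice is left to the converter.
* This is a library, not a command-line tool: the exported functions,
  the serializers (`write_triplets()`, `write_embedding()`,
  `write_fusion_dataset()`, ...) and this vignette are the interface.
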