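---
title: "Scoring KASP plate typing quality by multi-model fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring KASP plate typing quality by multi-model fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Kompetitive allele-specific PCR (KASP) genotypes a SNP by competing two
allele-specific primers labelled with different fluorophores. Each well of a
96-well plate yields an endpoint signal pair: relative HEX intensity $x$
(allele 1) and relative FAM intensity $y$ (allele 2). Plotting the 94 DNA
wells of an assay gives three clouds — homozygous allele 1 (high $x$),
homozygous allele 2 (high $y$) and heterozygous (intermediate) — plus two
no-template controls (NTC) that should stay at background. Whether a KASP
marker is usable for breeding work is judged from this scatter: tight,
well-separated clouds with the heterozygotes on the midpoint of the line
joining the homozygote clusters are ideal; shifted clusters, trailing tails
towards the origin, diffuse clouds, or amplification in the NTCs all reduce
quality.

`talsrx` scores a plate on the standard 0--100 rubric (eleven levels, steps
of 10) directly from the 192 raw fluorescence values
($2 \times 96$ wells, interleaved per well, DNA wells first). The scorer —
TAL-SRX — is a fusion of five models:

* **RS-RF**: a random forest tuned by random search;
* **PSO-SVM**: an RBF-kernel SVM tuned by particle swarm optimisation;
* **BO-XGBoost**: gradient-boosted trees tuned by Bayesian optimisation;
* a **stacked generalization** layer in which the SVM and RF produce 5-fold
  out-of-fold class probabilities ($2 \times 11 = 22$ meta-features) and the
  XGBoost model acts as meta-learner;
* an **ANN-LSTM** hybrid and a **Transformer encoder**, fused with the
  stacking output by weighted soft voting.

## The model

### Stacking

The training set $S = \{(y_n, x_n)\}$ is split into five equal disjoint
folds. Each base learner is trained on four folds and predicts class
probabilities on the held-out fold; concatenating the two learners' out-of-
fold probabilities gives the meta-feature matrix
$Z = \{Z_{\mathrm{svm}} \,\|\, Z_{\mathrm{rf}}\}$, on which the meta-learner
is trained against the original labels. Every row of $Z$ is produced by
models that never saw that sample, which is the property the test suite
verifies with a fold-frequency probe learner. At inference the base models
(refitted on the full training set, the common stacked-generalization
convention) produce probabilities that are fed to the meta-learner.

Two choices here were genuinely open. First, meta-features are
*probabilities*, not hard labels: they preserve ranking information and give
the meta-learner a 22-dimensional input, far below the 192 raw features.
Second, hyperparameter tuning runs once on the full training set before the
out-of-fold construction rather than nested per fold; this trades a small
optimistic bias in the meta-features for a fivefold reduction in tuning
cost, and matches a single-tuning workflow.

### Tuned base learners

The shipped default hyperparameters are the tuned reference configuration:

| model | configuration |
|---|---|
| RF | `n_estimators = 202`, `max_depth = 34`, `min_samples_split = 5`, `min_samples_leaf = 1` |
| SVM | `C = 695.65`, RBF kernel, `gamma = 0.0089` |
| XGBoost | `colsample_bytree = 0.87`, `learning_rate = 0.29`, `max_depth = 7`, `n_estimators = 139`, `subsample = 0.83` |

The default search spaces bracket these values (RF trees 50--400, SVM
$C \in [1, 10^3]$ and $\gamma \in [10^{-4}, 1]$ on log scales, XGBoost depth
3--10, learning rate 0.01--0.3), so the reference configurations are always
reachable. The tuning objective is mean 5-fold cross-validated accuracy,
maximised; ties keep the first-found configuration. The optimizer pairing is
fixed by default — random search for RF, PSO for SVM (canonical velocity
update with constriction constants $\omega = 0.72$, $c_1 = c_2 = 1.49$),
Bayesian optimisation for XGBoost — but can be overridden. The Bayesian
optimizer uses a squared-exponential Gaussian-process surrogate on unit-cube
coordinates (fixed length-scale 0.25, signal variance from the observed
responses, nugget $10^{-6}$) and proposes points by expected improvement
over a 500-point random candidate pool; a surrogate failure falls back to a
random proposal for that round. Integer parameters are handled by rounding
the continuous coordinate at evaluation time.

The SVM needs class probabilities for stacking and voting; we use the
standard pairwise-coupled sigmoid calibration of the one-vs-one binary
machines, seeded for reproducibility (the calibration involves an internal
cross-validation).

### Neural branches

Both branches are implemented in the package itself as explicit
forward/backward passes (verified against numerical gradients in the test
suite) trained with Adam on cross-entropy.

**ANN-LSTM.** The 192 features pass through a dense ReLU layer of 128
units; the embedding enters an LSTM cell with 128 units as a length-one
sequence (the most literal reading of reshaping a feature vector into a
sequence); the LSTM output maps linearly to the eleven logits. With a
zero initial state the forget gate multiplies zero, so the cell reduces to
input, candidate and output gates — the parameters are retained for
fidelity to the architecture. Defaults: `lr = 0.01`, 500 epochs, batch 32.
Inputs are standardised per feature inside the model (training mean and
standard deviation, reapplied at prediction): fluorescence features are all
positive, so without centring every input coordinate pushes a ReLU unit's
weights in the same direction, and at this learning rate Adam can kill the
entire dense layer within a few steps — a constant-predictor collapse that
centring removes.

**Transformer.** Each plate is tokenised as 96 wells $\times$ 2 channels.
A single 192-value token would make self-attention degenerate over a
length-one sequence, so one token per well is the natural choice; the
embedding width is `d_model = 48`, divisible by the `nhead = 6` attention
heads. Three encoder layers (multi-head self-attention, residual + layer
norm, position-wise feed-forward of width 96, residual + layer norm,
dropout 0.01 on both sub-layer outputs) are mean-pooled over tokens and
mapped to the logits. Wells are an unordered set, so no positional encoding
is added by default (a sinusoidal encoding is available behind a switch).
Defaults: `lr = 0.001`, 500 epochs, batch 32. Dropout is active only in
training; inference is deterministic.

### Soft voting

The three branch probability matrices are fused as
$P = \sum_m w_m P_m / \sum_m w_m$. The weights are found by exhaustive grid
search on the lattice $\{0, 0.05, \dots, 1\}^3$ (excluding the all-zero
point), maximising the accuracy of the fused argmax on an internal
stratified 15 % validation split; ties keep the earliest lattice point in
lexicographic order. The reference weight triple is
(stacking 0.95, ANN-LSTM 0.55, Transformer 0.25), which lies on this
lattice. After the search all branches are refitted on the complete
training set. Weights are normalised inside the vote, so any positive
rescaling leaves predictions unchanged.

Accuracy on a few-hundred-sample validation split is a coarse statistic: a
lattice point can "win" by a single reclassified sample. The package's
fitting paths therefore use a noise-aware selection
(`tol_samples = 1` in `grid_search_weights()`): every lattice point within
one misclassified validation sample of the maximum is treated as
statistically tied, and the tie is resolved by validation macro one-vs-rest
AUC (then lexicographic order). This prevents a one-sample fluke from
handing weight to a branch whose probabilities rank classes poorly, which
would silently degrade the fused model's discrimination. With
`tol_samples = 0` the function performs the plain exhaustive accuracy
maximisation.

## The synthetic plate simulator

No public corpus of labelled KASP plates exists, so the package ships a
generative simulator that realises each rubric class geometrically:

* signal levels: background 0.33, high 1.30 — the magnitudes of relative
  endpoint readouts on real plates (observed range roughly 0.28--1.43);
* genotype composition 40/40/14 (AA/BB/AB) of the 94 DNA wells — real
  plates vary; the composition is jittered per plate;
* clusters are isotropic Gaussians (`cluster_sd = 0.035`) around class-
  specific centroids; rubric clauses map to parameters: heterozygote
  offsets perpendicular to / along the homozygote line (classes 90, 80),
  homozygote shifts along their axis (70, 60), exponential trailing tails
  towards the origin (50; mean displacement 0.3 for 40 % of points),
  diffusion multipliers 2.2 / 3.2 / 5 / 8 for classes 40 / 30 / 20 / 0,
  and NTC displacement into the signal range for class 10;
* per-plate spec jitter of $\pm 20\%$ on all numeric parameters gives each
  class internal variation while keeping classes distinguishable;
* DNA well order is shuffled so that well position carries no genotype
  information, as on real plates.

Class balance is uniform by default: the per-score counts of real screening
populations are not publicly documented, and a uniform design isolates
model behaviour from imbalance effects.

The simulator emulates endpoint cluster *geometry* only. It does not model
PCR chemistry, cycle-dependent amplification, plate-batch effects,
instrument drift, or the label noise of human expert scoring. Passing tests
on simulated plates therefore demonstrates that the pipeline learns the
geometric rubric; it does not certify performance on any particular real
screening population, and headline accuracies on real proprietary datasets
are not reproducible here.

Geometric descriptors (`morphology_descriptors()`) quantify the rubric
clauses — per-genotype centroids and RMS spreads, the heterozygote's
(parallel, perpendicular) deviation from the homozygote midpoint, a tailing
index (skewness of projections onto the centroid-to-origin direction), a
separation index (minimum inter-centroid distance over mean spread), and an
NTC specificity index (maximum NTC distance from the estimated background
point over the mean genotype-centroid distance; the background point is the
per-axis 10th percentile of the DNA wells). These descriptors close the
loop: tests assert that simulated classes actually exhibit the geometry
their rubric row describes (noiseless class 100 has zero midpoint deviation
and spread; separation decreases monotonically along the diffusion classes;
only class 10 trips the NTC threshold of 0.5).

## Evaluation suite

Per class: precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, F1, and the
Jaccard-style ratio $TP/(TP+FP+FN)$. The last is reported under its own
name: it is sometimes printed as a per-class "accuracy", but it is a
different quantity from the headline overall accuracy (trace over total),
and the two cannot be conflated — the package exposes both. Macro averages
are unweighted means over classes present in the truth; classes with zero
denominators contribute zero. Cohen's kappa is $(p_o - p_e)/(1 - p_e)$ with
the six-level verbal band scale; one-vs-rest per-class kappas binarise each
class against the rest. One-vs-rest AUC uses the rank statistic with ties
counted one half (equivalent to exhaustive pair counting, which the tests
verify). Score-error vectors ($|{\Delta}\mathrm{score}|$) and score-band
histograms support error heatmaps and score-distribution comparisons.

## Numerical choices and degenerate inputs

* Single-class training data yields a degenerate constant classifier with a
  warning rather than an error (folds of extreme splits can be one-class).
* Classes absent from a training fold receive probability zero in the
  padded 11-class output.
* Backend probability outputs are renormalised per row to absorb
  single-precision round-off.
* Stratified splitting rounds the training size half-up and allocates
  per-class counts by largest remainder; a class with fewer than two
  members falls back to an unstratified split with a warning.
* All randomness flows from one root seed through a deterministic
  Lehmer-style stream-derivation (`derive_seed()`), making every fit,
  tuning run and benchmark bit-reproducible.
* A non-finite training loss aborts with the epoch and learning rate in
  the message rather than continuing silently.

## Benchmark scale

`run_benchmark()` trains the ten-model comparison (three tuned single
learners, two neural branches, stacking, and four voting combinations) on
a simulated population of 100 training and 30 test plates per class
(1430 plates) — large enough for stable metric ordering on a single CPU.
At this scale the benchmark configuration reduces the deep-branch epochs
(60 for ANN-LSTM, 14 for the Transformer) and uses small tuning budgets
(5--8 cross-validated evaluations per learner); the branch defaults keep
the full reference settings (500 epochs) for users who want them.

Within the benchmark, every compared model — single learners, stacking and
the voting combinations — trains on the identical 85 % sub-train pool, and
the fusion rows combine exactly the single rows' fitted models with
weights searched on the remaining 15 % validation split, which no model
saw. This all-else-equal convention matters at reduced epochs: Adam at
`lr = 0.001` shows a stochastic "breakout" time on this task, so two
transformer fits can differ substantially, and a fusion evaluated against
an independently refitted single model would be comparing two different
draws of that training noise rather than the value of fusion. The
production fitting function `tal_srx()` keeps the conventional refit: after
the weight search its branches are refitted on the complete training set.
The ANN-LSTM plateaus early on this task and typically receives a
near-zero weight — the intended behaviour of the fusion for a weak branch.

## Known limitations

* The simulator's verbal-rubric-to-geometry mapping is one reasonable
  formalisation; real plates exhibit morphologies (arcs, split clusters,
  plate-edge effects) it does not generate.
* The Transformer at benchmark epochs is far from converged; its standalone
  row underestimates what the architecture achieves at full budget.
* Grid-searched voting weights are selected on a 15 % validation split and
  can overfit it slightly on small populations; the refit-on-full-train
  convention mitigates but does not eliminate this.
* Only 96-well plate layouts (94 DNA + 2 NTC) are supported.
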