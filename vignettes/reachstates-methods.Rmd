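---
title: "Neural-state segmentation and decoding of reaching activity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-state segmentation and decoding of reaching activity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reachstates` models population spiking activity recorded while a subject
performs an instructed-delay reaching task towards one of nine targets
(three directions x three depths).  Each trial passes through four
behavioural epochs: **FREE** (hand on the home button, no cue), **DELAY**
(target visible, movement withheld), **MOVE** (the reach itself) and
**HOLD** (hand on the target until it switches off).  The package asks two
questions of such data: how many discrete *neural states* structure the
population dynamics, and how much information about task phase and reach
target can be read out from short fragments of activity.

## From spikes to symbol sequences

Spike trains of all simultaneously treated units are aligned to a
behavioural event, binned at 2 ms, and converted into *emission sequences*:
one symbol per bin, `0` for silence and `k` when unit `k` fired.  When two
or more units fire in the same bin, one of the active units is chosen
uniformly at random; repeating this stochastic reduction 100 times per
trial yields an ensemble of sequences that jointly retains the population
information a single sequence would lose.  A unit firing twice within a
bin emits its symbol once — symbols carry identity, not count.  Bins are
half-open, `[start, start + 2)` ms, so an event-time spike belongs to the
bin starting at the event.

The expected fraction of multi-unit ("collision") bins is computable from
the firing rates, and at the generator's default rates stays below 20%,
which keeps the distortion of the single-symbol reduction modest.

## Constrained hidden Markov models

Neural states are the hidden states of an HMM over these symbol sequences.
The transition matrix is constrained to a feedforward (Bakis) chain —
self-transitions plus steps to the immediately next state — matching the
one-way progression of the task.  Structural zeros are hard: training
never moves probability mass onto a masked transition.

Two estimators are provided:

* **Unsupervised (`baum_welch()`)** — multi-sequence EM with per-bin
  scaling.  Stops at 500 iterations or when the log-likelihood gain drops
  below `1e-6`.  Initial parameters are pseudo-random; emission rows can
  be initialized as random perturbations of the empirical symbol
  distribution (`empirical_from`), which with sequences hundreds of bins
  long avoids the degenerate optimum where the first state explains
  everything and later states are starved.  Because EM only finds local
  optima, `n_restarts` runs independent initializations and keeps the fit
  with the highest final log-likelihood.
* **Supervised (`supervised_fit()`)** — when epoch labels are available,
  the forward transition out of epoch `i` is `1 / (mean bins spent in
  epoch i)` and the emission probability of a symbol is its frequency
  among that epoch's bins.

Both estimators add a floor of `1e-6` to every emission entry (rows then
renormalized) so that the symbol of an unseen — or later removed — unit
never zeroes a likelihood; this is what lets the neuron-loss experiments
run without retraining.  Row-sum invariants are enforced to `1e-9`.

### How many states? The consistency analysis

For each candidate state count `K` in 2–7, one model per reach target is
trained on movement-centred sequences (1,000 ms before to 1,000 ms after
movement onset).  A held-out sequence is *consistent* with a model when
the posterior of every state reaches 0.7 at least once.  The selected `K`
is the largest one whose consistent fraction is at least 0.9 — a codified
form of the observation that two and three states are near-universally
consistent while four or more collapse.  On synthetic populations built
with the default task structure the analysis selects three states, whose
rise times align with movement onset and target touch; rise-time
variability can be corrected for behavioural-event jitter by subtracting
the event-time variance (`transition_timing()`, variance floored at zero).

## The 28-state boosted decoder

Decoding epoch and target jointly uses a composite model: nine two-state
HMMs (FREE/DELAY, trained on 500 ms either side of target onset) supply a
*shared* FREE state — emission row and self-transition averaged across
targets — and nine three-state HMMs (DELAY/MOVE/HOLD, trained on 1,000 ms
either side of movement onset) supply target-specific blocks.
`merge_boosted()` assembles `1 + 9 x 3 = 28` states: FREE may step into
any target's DELAY state (the leaving mass is split uniformly over
targets, a choice the construction leaves open), blocks are feedforward,
HOLD states are absorbing, and cross-target transitions are structurally
zero.

Fragments of the concatenated validation sequences (the last 500 ms of
FREE plus 2,000 ms centred on movement onset) are decoded independently:
the chain restarts in FREE for every fragment, posteriors are averaged
over the fragment's bins, and the state with the highest average is the
prediction, ties broken toward the earliest state in chain order.
Windows slide in 10-ms steps at widths of 50–300 ms; windows that would
straddle the seam between the two concatenated segments — a real temporal
discontinuity — are dropped.  True labels come from the epoch containing
the window midpoint in the trial's own event timeline; a midpoint exactly
on a boundary belongs to the later epoch (movement onset is MOVE).  The
interval between the go signal and movement onset (the reaction time) is
labelled DELAY, since the instructed behaviour is still being withheld.

The FREE restart has a diagnostic consequence: when a fragment's true
state is deep in the chain, the decoder must "pay" for the intermediate
transitions, so misclassifications skew towards epochs *preceding* the
true one, and populations whose FREE and HOLD activity patterns are
similar show a characteristic HOLD-to-FREE error (the FREE state acts as
an attractor).  The evaluation module quantifies both effects.

## Baselines

For algorithm comparison the same windows feed two conventional
classifiers over the same 28 classes:

* **SVM** (`svm_fit()`, via `e1071`/libsvm, one-vs-one multiclass) on
  per-unit mean firing rates per 200-ms window.  The grid search spans
  `C` in `{0.001, …, 1000}` with an RBF kernel and polynomial kernels of
  degree 2–8.
* **LSTM** (`lstm_fit()`) on the raw 2-ms binned counts of each window: a
  single LSTM layer, dropout on its final hidden state, a fully connected
  softmax output, trained with Adam while monitoring a held-out validation
  trial; the lowest-validation-loss parameters are retained.  The
  implementation is self-contained R (exactly reproducible given a seed)
  and sized for desk-scale populations; reference defaults are 200 hidden
  units, learning rate `1e-2`, minibatch 1,024 (auto-reduced on smaller
  training sets) and dropout 0.1.  Hyperparameter search beyond a small
  grid is out of scope.

## Evaluation battery

* **Accuracy vs chance** — accuracy is the fraction of correct window
  classifications; the chance distribution shuffles the true-label vector
  1,000 times.  The single "chance level" reported is the 95th percentile
  of that distribution (a conservative operationalization; the full
  distribution is kept).
* **Confusion matrices** — row-normalized over true classes; zero-support
  rows are flagged, never dropped.
* **Error patterns** — fraction of misclassifications assigned to epochs
  preceding vs following the true one, plus the named confusions
  DELAY-as-MOVE, FREE-as-MOVE and HOLD-as-FREE.
* **Target geometry** — the nine targets are placed in the horizontal
  plane from their version angles (−15°, 0°, +15°) and radial distances
  (10, 15, 25 cm); vergence angles are redundant given the distances and
  are not used.  The distance–confusion correlation (Pearson by default,
  Spearman optional) relates symmetrized off-diagonal confusion
  probabilities to pairwise target distances over the 36 unordered pairs;
  a uniform confusion matrix is defined to have zero correlation.
* **Clustering indices** — the Davies–Bouldin index over per-(trial,
  epoch) mean-rate vectors, with the pairwise scatter/separation ratio
  (`r_metric()`) exposed because the FREE-vs-HOLD ratio is itself
  diagnostic.  Feature vectors are *not* standardized for the index (raw
  firing rates); the t-SNE embedding standardizes per unit.  Bootstrap
  distributions resample units without replacement (90% of the
  population, or a fixed 40 units); infinite index values (coincident
  centroids) are excluded from summaries with a recorded count.
* **Robustness** — `neuron_loss()` removes increasing numbers of units
  *after* training (sequences regenerated without the removed units for
  the HMM and LSTM; SVM features zeroed); `noise_injection()` keeps each
  perturbed unit-trial's first and last spikes and redraws the interior
  spike times uniformly between them (count preserved; an inter-spike
  interval permutation is available as `method = "isi"`).  Within one
  bootstrap the removal sets are nested — a random unit order is drawn
  once and level `k` removes its first `k` units — so each bootstrap
  traces a single degradation trajectory, which reduces between-level
  sampling noise.  `subsample_curve()` instead retrains on random subsets
  in five-unit steps and reports the minimum population size reaching 50%
  accuracy.
* **Comparisons** — nonparametric Wilcoxon tests over bootstrap or fold
  samples (`compare_conditions()`).

## The synthetic task generator

Everything above is exercised on synthetic data, so the generator is part
of the tested surface.  `make_task_schedule()` reproduces the task's
timing: 1,000 ms FREE, 1,800–2,300 ms delay, an 800–1,200 ms hold, and a
movement duration centred near 360 ms; the reaction time (go signal to
movement onset) is drawn uniformly from 200–400 ms, a choice that keeps
movement-onset variability realistic for the variance-correction
analysis.  `simulate_spikes()` emits per-unit Poisson spike trains whose
rate in each epoch is `baseline x epoch gain x target tuning`, capped at
100 sp/s to avoid saturating 2-ms bins.  All randomness flows from one
seed through a documented substream scheme (one substream per unit and
trial), so datasets are bit-reproducible.

Baseline rates are log-normal (median 5 sp/s).  Epoch gains are drawn per
unit and per epoch from log-normal distributions around epoch-specific
means, so each epoch has a distinct population-wide activation *pattern*
(some units up-, some down-modulated) rather than a shared scalar — a
shared scalar would make HOLD a scaled copy of FREE and no decoder could
tell them apart.  Target tuning is multiplicative and spatially smooth:
each unit has a Gaussian sensitivity bump with a random centre over the
3 x 3 target grid, exponentiated and normalized to mean 1, so nearby
targets have correlated rates (which is what makes target confusions
distance-dependent).

Three presets emulate the qualitative contrasts between the recorded
parietal populations:

| profile | target tuning amplitude | epoch-gain contrast | FREE vs HOLD |
|---|---|---|---|
| `V6A-like` | strong (1.5–2.5) | strong | distinct |
| `PEc-like` | intermediate (0.5–1.0) | strongest | distinct |
| `PE-like` | weak (0.1–0.3) | weak | near-identical per unit |

No quantitative tuning parameters are available for the real areas, so
the presets are calibrated to reproduce *orderings and motifs*, not
absolute values: target-cluster overlap (Davies–Bouldin) increases
V6A-like < PEc-like < PE-like; the PE-like FREE/HOLD scatter ratio
exceeds the V6A-like one; and high-SNR V6A-like populations support
epoch/target decoding well above chance while PE-like ones show the
HOLD-as-FREE attractor error.  The generator deliberately omits
refractory periods, spike-history dependence, correlated noise across
units, non-Poisson count variability and eye-position signals — so
passing tests demonstrate the *pipeline's* correctness and the
qualitative transfer of the experimental designs, not quantitative
reproduction of recorded data.

## Numerical choices and problem sizes

* Forward–backward uses per-bin scaling (log-likelihood from the scaling
  constants) and iterates only the structurally allowed transitions, so
  chain and block topologies cost `O(T x edges)`.
* Times are stored at 0.1 ms resolution; all windows are half-open.
* The test suite and the acceptance script run at desk scale, chosen to
  keep the full battery within minutes while leaving the statistical
  margins comfortable: consistency analysis over 5 population seeds with
  10 sequence repeats and 2 EM restarts; end-to-end decoding on one
  cross-validation fold with 10–15 repeats and 3 restarts; perturbation
  curves with 6 bootstraps over removal levels `{4, 16, 32}` of a 40-unit
  population.  Defaults in the package remain the full-scale settings
  (100 repeats, 500 iterations, 10 folds, 25/10 bootstraps).
* Parameter-recovery checks compare against exact oracles: path
  enumeration for posteriors, and a Poisson-binomial dynamic program for
  the per-bin symbol distribution implied by the rates and the collision
  rule.

## Known limitations

* The unsupervised fit can still land in a poor local optimum for
  pathological draws; restarts reduce but do not eliminate this.
* The LSTM baseline is deliberately small; it demonstrates the comparison
  design, not state-of-the-art sequence classification.
* The 2-D embedding is an exact (non-approximate) t-SNE suitable for a
  few hundred points; it is for visualization only and no quantitative
  conclusion rests on it.
* Because the generator's target tuning is constant across epochs (the
  rate model is `baseline x epoch gain x target tuning`), spatial
  information does not concentrate in the movement phase the way it does
  in recordings, where spatial selectivity is itself epoch-dependent.
  The decoding time course on synthetic data therefore need not peak
  during MOVE; reproducing that temporal profile would require
  epoch-dependent tuning, which is deliberately outside the generative
  model.
* Real recordings pooled across sessions ("pseudo-populations"), drifting
  units and correlated noise are outside the generator's scope; an
  adapter for deposited datasets would need its own validation.
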