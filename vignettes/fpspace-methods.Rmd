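---
title: "Classification spaces for fixed-point networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification spaces for fixed-point networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpspace)
```

## The model

A fixed-point network responds to a sustained stimulus with a transient
that settles near a stable activity pattern. Supervised recordings give,
per stimulus $S_i$ and trial, a nonnegative firing-rate matrix
$F_{S_i} \in \mathbb{R}^{N \times T}_{\ge 0}$ (nodes × time). `fpspace`
builds a classification state space in three steps.

**Per-stimulus dimension reduction.** `svdsep()` decomposes each
(trial-averaged) $F_{S_i}$ as $F = \sum_k \vec a_k(t)\, \vec g_k$, with
orthonormal node-space patterns $\vec g_k$ and time coefficients
$a_k(t) = \sigma_k \alpha_k(t)$. The relative energies
$H_k = \sigma_k^2 / \sum_j \sigma_j^2$ quantify how dominant each pattern
is; fixed-point responses are near rank one per stimulus, so $H_1$ is
large for each stimulus separately but not for the concatenated
collection (`svdcon()`), whose dominant mode mixes correlated stimuli.
The dominant patterns form the columns of the library
$L \in \mathbb{R}^{N \times m}$. Singular-vector signs are fixed by
requiring a nonnegative column sum — the dominant pattern of a
nonnegative matrix always has such a representative — without which a
per-row maximum rule would be meaningless.

**ETR.** `etr()` keeps, in each row of $L$, only the maximal entry if it
exceeds a threshold $\tau \ge 0$ (default 0, the common case), zeroing
everything else. Each node is assigned to at most one stimulus; the
resulting $O$ has disjoint column supports, hence $O^\top O$ is exactly
diagonal — the basis is orthogonal by construction, not to a tolerance.
Row ties go to the lowest stimulus index, which makes the operation
deterministic; the rule is positively homogeneous
($\mathrm{etr}(cL, c\tau) = c\,\mathrm{etr}(L, \tau)$).

**OETR.** ETR leaves the projected fixed points $L^\top O$ diagonal-ish
but not orthonormal. `oetr()` finds the diagonal re-weighting $D^w$
solving $\min_w \lVert L^\top D^w O - I\rVert_F$. Every entry of
$L^\top D^w O$ is linear in $w$, and because $O$'s columns have disjoint
supports the problem separates into one small least-squares system per
stimulus; each is solved in closed form by a minimum-norm SVD solution.
When a stimulus has more assigned nodes than there are constraints the
system is underdetermined and the minimum-norm convention makes the
returned weights reproducible. Weights are unconstrained in sign; nodes
left unassigned by the threshold get $w = 0$ by convention (their weight
never enters the objective). A stimulus with no assigned node triggers a
diagnostic warning — the identity is unreachable on that axis — but the
minimizer is still returned.

**Recognition.** `project_response()` maps a response to
$x(t) = B^\top f(t) / s$ with $B = D^w O$. The recognition region is an
$m$-dimensional hyperellipse at center $c$ with radii $r$:
$q(x) = \sum_i ((x_i - c_i)/r_i)^2 - 1$, inside iff $q \le 0$ (the
boundary counts as inside). The Rec score of a trajectory is the
fraction of stimulus-ON samples inside. Stimulus-level classification
normalizes the per-stimulus mean scores by their maximum and thresholds
them at the decision line $d = (\text{mean} + 1)/2$, strictly: a score
exactly at $d$ is non-behavioral. Reported accuracy is precision ×
recall, with empty denominators reported as 0. Single-trial recognition
accepts a trial whose Rec reaches 70 % (configurable) of the Rec of the
target's trial-averaged trajectory; the alternative reading of that
contract as a fixed 400 ms duration is treated as illustrative and is
not implemented.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau` (ETR threshold) | 0 | library units | keep every positively responding node; raise to drop weakly tuned nodes |
| `radius` | 0.65 | fixed-point units | hypersphere radius for the target region; sweeps use 0.5–0.85 |
| `threshold_frac` | 0.7 | fraction | single-trial recognition threshold relative to the target trajectory's Rec |
| `alpha` (confidence) | 0.01 | two-sided level | 99 % Student-t intervals on per-trial Rec; seeded bootstrap percentile optional |
| `dt`, ON window | 10 ms, [0, 0.5) s | s | 1 s recordings, stimulus ON during the first half; all configurable |
| PSTH kernel width | 50 ms | s | Gaussian instantaneous-rate estimate, boundary-truncated and renormalized so spike counts are conserved |

Projection **scale**: the fixed points of the basis live at unit
coordinates ($L^\top D^w O \approx I$), but raw firing-rate trajectories
project to coordinates of the order of the pattern norm (~10²
spikes/s·√nodes). `build_space()` therefore stores a single scalar — the
mean own-axis coordinate of the trial-averaged training responses over
the plateau (second) half of the ON window — and projections are divided
by it. One global scalar, rather than per-axis scaling, keeps the
geometry rigid; hyperellipse radii are then expressed in fixed-point
units, where the defaults above are meaningful. Spaces built directly
from a library (no training data) use scale 1.

ICA axes (`ica_basis()`, delegated to `ica::icaimax`, run on $L$ without
centering since the node-mean of a nonnegative library carries its
dominant shared mode) are greedily matched to stimuli by absolute
correlation with the library columns and sign-oriented positively, so
that centers and radii are comparable across methods. Non-convergence is
flagged on the result, not raised.

## The synthetic generator

`generate_benchmark_like()` emulates the structure of a population
recording from an olfactory fixed-point network: `nodes = 106`,
`n_stimuli = 8` mono-molecular stimuli, 5 trials, 1 s at 10 ms sampling,
ON window [0, 0.5) s, plus nine planted mixtures — three behavioral
blends of stimuli 1–3 (B1 equal-weight, B2/B3 near-equal perturbations),
five non-behavioral mixtures (the blend missing one constituent, the
constituent replaced by another odorant, and unrelated blends), and a
noise-only control — 17 stimuli, 85 trials in total.

Choices and their rationale:

* **Patterns.** Per-node amplitudes are Uniform(20, 60) spikes/s, a
  realistic projection-neuron firing range. `support_overlap = 0.15` of
  nodes respond to every stimulus (distinct weights); the rest split
  disjointly. This overlap reproduces the qualitative energy structure
  of real odor population codes, where the concatenated decomposition is
  dominated by a single shared mode ($H_1$ well above the $1/m$ of
  uncorrelated patterns) while per-stimulus decompositions are near rank
  one. `support_overlap = 0` gives exactly recoverable ground truth for
  the recovery tests.
* **Envelope.** $a(t) = 1 - e^{-t/\tau_\text{rise}}$ during ON with
  $\tau_\text{rise} = 100$ ms — trajectories reach the fixed point's
  vicinity within 200–400 ms — and exponential decay after OFF.
* **Noise.** I.i.d. Gaussian per sample, clipped at zero, with variance
  set so that (time-averaged ON signal power per node, averaged over
  assigned nodes) / variance equals the configured SNR; default `snr = 3`,
  the low-SNR regime typical of multi-unit recordings. The
  Gaussian approximation to PSTH noise is good at moderate rates; at
  `snr` ≲ 3 the clip is no longer negligible for weakly tuned nodes, so
  the Monte-Carlo SNR checks are run in the moderate-rate regime where
  the model's assumption holds. A Poisson-spike path through
  `spikes_to_psth()` exercises the PSTH conversion as an alternative.
* **Mixtures** are linear superpositions of constituent patterns. Real
  mixture responses are not purely concentration-additive; no sublinear
  suppression is applied by default, so tests exercise the geometry, not
  mixture nonlinearity.
* **Determinism.** The whole collection is a pure function of the
  config and seed; trial noise streams are derived from
  (seed, stimulus, trial), so trials share the signal and differ only in
  noise.

**What the generator does not emulate — and what passing tests therefore
do not show.** Real PSTHs are smoothed spike-rate estimates, so their
noise is temporally correlated; the generator's i.i.d. per-sample noise
is spectrally much harsher at matched SNR. Consequences: at `snr = 3`
single-trial trajectories under an OETR basis (whose cancellation
weights amplify independent noise) can spend zero ON samples inside a
0.65-radius region even though the trial-averaged geometry is perfect,
and the classification accuracy a real recording at SNR < 3 can reach
will generally exceed what this generator yields at the same nominal
SNR. The high-SNR (`snr = 10`) results — perfect accuracy for every
space dimension $m \ge 3$, below 1 for $m \le 2$ — characterize the
method's geometry, not its robustness to realistic correlated noise.
There is also no spike sorting noise, no cross-trial drift, and no
odorant chemistry.

## Numerical choices and degenerate inputs

* All-zero matrices have no energy spectrum and cannot be decomposed:
  degenerate-input errors, not NaNs.
* ETR orthogonality is asserted with zero tolerance (disjoint supports
  are exact); OETR optimality is validated against an independent
  closed-form least-squares oracle at 1e-6; SVD reconstruction at
  1e-6·‖F‖; noiseless fixed-point orthonormality at 1e-8.
* Tied singular values keep the solver's order (energies are
  unaffected); tied ETR row maxima go to the lowest stimulus index.
* All mean Rec scores zero means nothing falls inside the target region:
  `classify_behavioral()` raises a degenerate-input error, while sweep
  helpers (`radius_sweep()`, `accuracy_by_snr()`) count such runs as
  precision = recall = 0.
* Collection CSVs are written with 17 significant digits so that
  save/load round-trips are bit-exact.
* RUSBoost implements the pseudo-loss
  $\epsilon_t = \sum_{(i,y):y_i \ne y} D_t(i)\,(1 - h_t(x_i,y_i) + h_t(x_i,y))$
  literally; with this form the vote weight $\log(1/\alpha_t)$,
  $\alpha_t = \epsilon_t/(1-\epsilon_t)$, is positive exactly when
  $\epsilon_t < 0.5$, so rounds at or above 0.5 are discarded and
  resampled (bounded retries). $\epsilon_t = 0$ is clamped to $10^{-10}$.
* Mixture hyperellipse centers come from the mean projected training
  trajectory over the ON window, because the basis defines fixed-point
  coordinates only for the library stimuli; for those, the fixed-point
  row of $L^\top D^w O$ is used directly.

## Problem sizes used by the test suite

Unit tests run on collections of 12–106 nodes with 2–5 trials; the
end-to-end recovery checks use the full 106-node, 17-stimulus, 85-trial
configuration at SNR 10, and the degradation sweep averages 20 seeded
collections per SNR in {10, 3, 1, 0.3}. The whole suite completes in
well under a minute on one core; these sizes were chosen as the smallest
that keep every check in its intended statistical regime.

## Known limitations

* The decision line $d$ assumes at least one clearly scoring stimulus;
  with all-zero scores classification is refused rather than guessed.
* OETR weight magnitudes are unbounded; with very few assigned nodes per
  stimulus the cancellation weights amplify noise (visible as the sharp
  accuracy drop between SNR 10 and 3 in the degradation curve).
* The convex-hull classifier of which the hyperellipse is a
  simplification is not implemented, nor are sparse (L1) decompositions.
* SMOTE-style oversampling is out of scope; class imbalance is handled
  by random under-sampling inside RUSBoost.
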