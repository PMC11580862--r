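---
title: "Ensemble Kalman filtering on agent-based models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble Kalman filtering on agent-based models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mechanistic agent-based models (ABMs) of cellular biology — immune
responses, infection dynamics, ecological analogues — are stochastic,
spatially heterogeneous, and carry far more state than any realistic
measurement can observe. Personalizing such a model to an individual means
repeatedly recalibrating it from sparse, noisy, aggregate measurements:
a data-assimilation problem. The obstacle is the gap between the
**microstate** — every agent's position, energy, internal category, every
lattice value, everything needed to advance the simulation — and the
**macrostate** — the low-dimensional summary (counts, totals, averages)
that corresponds to what can actually be measured.

Classical Kalman filtering cannot act on microstates directly: their
dimension changes as agents are born and die, there is no natural
correspondence between agents of different ensemble members, categorical
lattice states are not vectors, and treating spatial fields as flat vectors
is hopeless — `covariance_entry_count(12, 51, 51)` shows that twelve
molecular fields on a 51 x 51 lattice alone would imply roughly half a
billion covariance entries to estimate.

`abmkf` therefore filters macrostates and closes the loop with **microstate
synthesis**: constructing, for each filtered macrostate, a full microstate
that is both exactly compatible with it and plausible under the model's
dynamics.

## The assimilation loop

One cycle of `run_abmkf()`:

1. **Advance** every member's microstate with the simulator, each member
   under its own parameter values.
2. **Summarize** the microstates into transformed macrostate vectors.
3. **Update**: an ensemble Kalman filter conditions the macrostate ensemble
   on the new measurement, producing a Gaussian posterior.
4. **Resample** a fresh macrostate ensemble from that posterior.
5. **Synthesize** a compatible microstate for every posterior sample,
   seeded from the predictive member it is stable-matched to.

The prior is Gaussian in transformed macrostate space over both the
observable components and the individual-level model parameters
(augmented-state filtering). Initial microstates are realized from prior
draws through the model's known onset configuration — at the start of an
experiment the fine-grained configuration is the one situation where the
microstate is essentially known.

## Macrostate design

Macrostate components are quantities that are permutation-invariant over
agents, stable over short times, and plausibly measurable: agent counts per
type, totals of spatially distributed fields, and cumulative event
counters. Model parameters that vary between individuals are appended as
additional components so the filter estimates them jointly with the state.

A least-squares filter learns the largest-magnitude components and treats
the rest as noise, so per-component **transforms** matter:

* `transform_log_eps(eps)`: `x' = log(eps + x)` with inverse
  `max(0, exp(x') - eps)`, `eps = 0.001`. Used for counts whose
  distribution concentrates at zero — wolf counts near extinction, viral
  loads — while remaining defined at exactly zero.
* `transform_scale(c)`: brings components of different magnitude to a
  common range. The default wolf-sheep-grass schema scales sheep by 0.1
  and the grass-patch count by 0.01, since these run one and two orders of
  magnitude above the (log-)wolf count.
* Parameter components are carried in units that already sit in the same
  range as the transformed state: reproduction probabilities are expressed
  **in percent** (4%, 5% become 4, 5 — the same order as log-wolf counts),
  so they need no transform and a per-step random-walk variance of
  `q_param = 0.01` is a sensible default.

Values stay real-valued throughout the filter; rounding to integer counts
happens only inside synthesis (largest-remainder rounding, so category
totals are met exactly).

## The ensemble filter

`enkf_update()` implements the classic stochastic (perturbed-observation)
ensemble Kalman filter: fit a sample Gaussian (denominator n−1) to the
predictive ensemble, update every member with an independently perturbed
observation using the sample-covariance gain, fit a Gaussian to the updated
members, and draw a fresh same-size ensemble from it. Resampling (rather
than propagating the updated members) hands the synthesis step a clean
posterior sample. A diagonal jitter of `1e-8` is added before sampling:
ensembles genuinely degenerate near absorbing states (species extinction),
and the filter must keep operating there.

Process noise is added **only to the parameter components**
(`add_parameter_process_noise()`): the simulator supplies its own
stochasticity for the state, and the random walk on parameters is what
lets the filter revise its parameter estimates between measurements. The
virtual patient's own parameters stay constant; noise applies to the
ensemble only.

The exact linear Kalman filter (`kf_predict()`, `kf_update()`) is included
as the closed-form oracle that the ensemble filter is tested against.

## Microstate synthesis

Two principles guide the design:

* **Continuity** — nearby macrostates should be realized by nearby
  microstates. Posterior samples are therefore paired with predictive
  members by a Gale–Shapley stable matching (`pair_ensembles()`) under
  mutual distance preferences in transformed macro space, and each
  posterior sample is synthesized *from* its paired member's microstate.
  Posterior samples propose; ties break toward the lower index, making the
  matching deterministic given the inputs.
* **Local similarity** — in spatial models, changes should respect
  existing geometry: agents in similar neighborhoods behave similarly, so
  a synthesized microstate should not scatter category changes at random.

For the spatially well-mixed predator-prey model, uniform-random synthesis
is the *correct* realization of these principles: positions are
approximately uniform in equilibrium, so `synthesize_wsg()` adds agents at
uniform positions (energies resampled from the surviving agents' empirical
distribution — the model's own history is the best available likelihood)
and flips grass patches uniformly among the eligible ones.

For the viral model, spatial structure is the point, and two algorithms are
provided. `simple_synthesis_viral()` relabels uniformly chosen sites — the
minimum number of changes (half the L1 distance between count vectors), but
blind to geometry: it fragments infection hot-spots. The spatially aware
route handles each categorical lattice in three steps:

1. **One-hot encode** (`one_hot_encode()`): category i becomes the basis
   vector e_i, so category counts are the site-sum of the field.
2. **Rescale** (`rescale_onehot()`): multiply component j everywhere by
   `new_count[j] / old_count[j]`. The site-sum now equals the target
   counts while every site keeps its local composition. A category absent
   from the seed but present in the target has no spatial information and
   is spread uniformly.
3. **Quantize with error diffusion** (`quantize_error_diffuse()`): return
   every site to a basis vector while preserving the counts. Sites are
   visited in a seeded random permutation (raster order would push
   hot-spot edges directionally); at each site the algorithm picks the
   feasible category minimizing

   `L(q) = lambda1 |q - s|^2 + lambda2 (-log(c.q + smoothing)) + lambda3 (-log p(neighborhood))`

   — quantization error, dissimilarity to the 3 x 3 neighborhood (`c` is
   the regularized neighbor-category count; this discourages isolated
   types), and the negative log-probability of the resulting neighborhood
   under a histogram model trained on previous runs
   (`build_neighborhood_model()`, add-one smoothing, eight log-spaced bins
   per molecular field). The residual `q - s` is diffused uniformly over
   the not-yet-quantized Moore neighbors, so total vector mass — and hence
   the count macrostate — is conserved mid-pass; residuals with no
   unquantized neighbor go to a global pool.

Feasibility quotas guarantee exact target counts, but they also force the
last-visited sites into whatever categories remain — which would scatter
precisely the surplus categories the update added. The final
**exchange repair** fixes this: relabel cycles over categories (one site
per arc, so all counts are preserved) are cancelled while they reduce the
loss. When the neighborhood terms are off (`lambda2 = lambda3 = 0`) the
loss is site-separable and the absence of a negative relabel cycle is
exactly the optimality condition of the underlying transportation problem,
so the repair provably terminates at the count-constrained optimum. With
neighborhood terms active the loss table is recomputed after every
cancellation and the loop is iteration-capped; in practice this is what
moves quota-forced isolated infected sites to hot-spot boundaries, and it
is the difference between mildly and decisively beating the simple
synthesis on spatial coherence.

Molecular fields need none of this: `rescale_molecular()` multiplies the
field by `new_total / old_total`, preserving spatial correlations exactly.
Immune agents are removed uniformly or added at sites drawn proportional
to the proinflammatory field; nothing forces a particular mobile-agent
synthesis rule, and chemokine-weighted placement is this package's choice.

## The two bundled models

**Wolf-sheep-grass** (`wsg_params()`, `step_wsg()`): the classic
predator-prey ABM. The step is synchronous with substep order
move → eat → reproduce → die → regrow; turn angles are uniform in ±50°,
speed is one patch-length per step, movement costs one energy — the
reference model's conventions, since "random walk" alone does not fix
them. Every sheep standing on a grassy patch at the start of the eat
substep gains energy (the synchronous reading); a wolf eats at most one
co-located sheep, chosen uniformly, and wolves eat distinct prey.
Reproduction splits the parent's energy exactly in half with a child at
the same position. Grass regrows on a fixed timer.

**Minimal viral model** (`viral_params()`, `step_viral()`): a deliberately
simplified stand-in for full-scale immune-response ABMs, keeping exactly
the features the synthesis machinery needs: a five-category epithelial
lattice (healthy / infected / necrosed / apoptosed / empty), a
three-category endothelial lattice (normal / activated / dead), molecular
fields, mobile immune agents, and a counter of epithelial cells apoptosed
by the virus. Design notes:

* The cytokine collection has **three** fields — antiviral-like (type-I
  interferon), proinflammatory-like, and a DAMP-like damage signal —
  because the stated dynamics need a damage channel: necrotic sites emit
  DAMPs and endothelium dies above a local DAMP threshold.
* Infected sites emit the antiviral cytokine as well as virus and
  proinflammatory cytokine; without an interferon source the antiviral
  modulation of apoptosis would be inert.
* Diffusion is explicit five-point with zero-flux boundaries, stable for
  coefficients ≤ 1/4 (enforced); decay is multiplicative, so fields stay
  nonnegative.
* Default rates (`infect_rate = 0.1`, per-field decay 0.12–0.15, virus
  production 1 per step) were chosen once so that a single seeded
  infection on a 25 x 25 lattice grows as a contiguous hot-spot over
  roughly 150–200 steps rather than either dying out immediately or
  consuming the lattice in a few dozen steps; they were not revisited.
  The default lattice is 51 x 51; tests use 25 x 25 for speed.

## Evaluation

* `gaussian_surprisal()` scores a forecast by the negative log density of
  the true transformed macrostate under the predictive Gaussian — unlike a
  distance to the ensemble mean it rewards honest uncertainty. It is
  evaluated on the full augmented state (parameters included), because the
  filter's parameter uncertainty is part of the forecast.
* `tuning_sweep()` reproduces the tuning protocol: simulate a cohort of
  virtual patients, run the filter at each (measurement, uncertainty)
  setting, and compare pointwise median surprisal series.
* `gaussian_wasserstein2()` implements the closed-form W2 between
  Gaussians (matrix square roots by symmetric eigendecomposition, negative
  eigenvalues clipped at zero).
* `phenotype_clustering()` flattens trajectories, reduces by PCA to three
  components, and clusters by k-means with ten seeded restarts; k is
  chosen by mean silhouette width over k = 2..k_max (silhouette is this
  package's selection rule, with a single-cluster fallback when all
  trajectories coincide).
  Per-cluster per-time Gaussians and their pairwise W2 series localize
  *when* phenotypes diverge.

## What the synthetic data does and does not establish

All experiments here are twin experiments: the "patient" is itself a model
run with known parameters, measurements are simulated with the stated
noise, and the generator's defaults are the stated world (ensemble 50,
horizon 200, measurements every 20 steps, measurement variance 0.01 on the
transformed sheep count, parameter process noise 0.01). A green test
establishes that the algorithm assimilates, recovers parameters, and
preserves spatial structure *for models with these characteristics* —
well-mixed predator-prey dynamics and focal spatial infection. It does not
establish clinical validity of any particular disease model, fidelity of
the minimal viral model's immunology, or robustness to model error
(patient generated by a different model than the filter uses), none of
which are exercised.

## Numerical choices

* Covariance symmetrization everywhere; eigenvalue clipping at zero before
  sampling or matrix square roots; `1e-8` jitter in the ensemble update;
  `1e-10` jitter before surprisal evaluation.
* Largest-remainder rounding turns real-valued count targets into integer
  targets with exact totals; ties break toward the lower index.
* Prior draws and posterior samples are clamped to valid domains at the
  model boundary (counts ≥ 0, grass ≤ patch count, probabilities in
  [0, 1]); the eps-log inverse already clamps at zero.
* Four named random streams (patient, ensemble, filter, synthesis), each
  derived from the experiment seed; runs are bit-for-bit reproducible.

## Known limitations

The filter is Gaussian and unimodal. When the model has several absorbing
or near-absorbing regimes that the chosen measurement cannot distinguish —
wolf-free worlds with either many sheep or none, diverging infection
phenotypes mid-course — a minimum-mean-square-error estimate sits between
the modes, and a sampling accident can lock the filter into the wrong
basin, where further measurements of the same component cannot correct it.
The surprisal series makes such failures visible (sustained spikes), but
the present algorithm does not fix them; stratified or mixture filtering
would be the natural extension. Spatially aware synthesis assumes the
category mass rescaling is meaningful, i.e. the update is modest relative
to the seed state; order-of-magnitude macrostate jumps degrade it toward
the simple algorithm's behavior.
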