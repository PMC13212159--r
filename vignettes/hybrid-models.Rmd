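---
title: "Hybrid neural-cognitive models of reward learning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid neural-cognitive models of reward learning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `hybridrl`, the
assumptions behind the synthetic-data generators, and the numerical and
design decisions a user should know before trusting (or extending) the
results. Everything quantitative stated here is computed by the package's
test suite or by the scripts under `analysis/`.

## The task

The restless four-armed bandit: on each of 150 trials the agent picks one
of four arms and receives an integer reward between 1 and 100 points. Each
arm's latent mean follows a mean-reverting Gaussian random walk,

$$\mu_{t,i} \sim N\!\big(\lambda\,\mu_{t-1,i} + (1-\lambda)\,50,\ \sigma_d\big),
\qquad r_{t,i} \sim N(\mu_{t,i}, \sigma_o),$$

with defaults $\lambda = 0.9836$, $\sigma_d = 2.8$, $\sigma_o = 4$ and
uniform initialisation on $[1, 100]$. Observed rewards are rounded and
clipped to $[1, 100]$; the latent means are not clipped (the package treats
clipping as a display property of the task, not a property of the walk —
the walk's stationary distribution keeps means well inside the range
anyway, so the choice is inconsequential in practice). All models consume
rewards divided by 100, i.e. on $[0.01, 1]$: this bounds prediction errors
by 1, which the Pearce-Hall rule requires for its learning rate to stay in
$[0, 1]$, and it puts value logits on a scale where softmax temperatures
are interpretable.

Performance is summarised as *relative reward*: per trial,
$(r_t - \mathrm{mean}(p_t)) / (\max(p_t) - \mathrm{mean}(p_t))$ where
$p_t$ is the four-arm reward vector, so 0 is random choice and 1 is the
(unattainable) per-trial optimum.

## The tabular model family

The core update is the biased delta rule
$Q \leftarrow Q + \alpha (r - Q) + b$, with softmax choice
$p = \mathrm{softmax}(\beta (Q + c))$. Optional mechanisms:

* **Perseveration**: $c(a_{t-1}) = \kappa$, all other entries 0. Negative
  $\kappa$ expresses switching.
* **Forgetting**: exponential decay of action values towards the initial
  value, $Q \leftarrow (1-f) Q + f\,Q_{\mathrm{init}}$.
* **Variable learning rate** (Pearce-Hall): $\alpha_{t+1} = w |\delta_t| +
  (1-w) \alpha_t$, replacing the fixed $\alpha$ with an initial value
  $\alpha_{\mathrm{init}}$.

Per-trial order of operations: decay, then the chosen arm's update from
its post-decay value, then the perseveration vector, then the next
choice's policy.

Two decisions deserve comment:

* **Decay scope.** The descriptive text and figures for the winning
  handcrafted model describe decay of *unchosen* action values, while the
  formal definition says all values decay. The package's default decays
  unchosen arms only, and the variant grid carries an explicit
  "decay-all" setting so both readings are fitted and compared rather
  than silently chosen.
* **The 48-variant grid.** The variant family is the full product
  {bias} x {perseveration} x {variable learning rate} x {free
  $Q_{\mathrm{init}}$} x {forgetting: off / decay-unchosen / decay-all}
  = 2·2·2·2·3 = 48. This reproduces the documented family size and
  contains Simple RL (free $\alpha, \beta$ only) and Best RL (six free
  parameters: $\alpha, \beta, f, \kappa, b, Q_{\mathrm{init}}$, decay of
  unchosen values) as members; the original count is not decomposed in
  the source material, so the factorisation is this package's own.

Fitted parameters are constrained by smooth transforms of unconstrained
raw values: sigmoid onto $(0,1)$ for $\alpha$, $\alpha_{\mathrm{init}}$,
$f$, $w$; tanh onto $(-1,1)$ for $b$, $\kappa$; softplus onto $(0,\infty)$
for $\beta$ (a hinge would have zero gradient at the boundary; softplus
keeps the fit informative near $\beta = 0$); identity for
$Q_{\mathrm{init}}$. Variants without a free $Q_{\mathrm{init}}$ initialise
values at 0.5, mid scale.

## The neural architectures

All four networks share the structure "two-layer perceptron with tanh
hidden layer and linear output", so outputs are logits/values directly.

* **RL-ANN**: a reward module mapping $[Q_{t-1}(a),\ r_{t-1}]$ to the
  chosen arm's new value, and an action module mapping the scalar
  previous action to the four-vector perseveration $c$. Unchosen values
  decay exponentially towards a trainable $Q_{\mathrm{init}}$ with a
  trainable rate (stored raw, sigmoid-transformed). Logits are $Q + c$;
  there is no inverse temperature — the scale lives in the output
  weights.
* **Context-ANN**: identical, but the reward input also carries the full
  $\mathbf{Q}_{t-1}$ vector and the action input the full
  $\mathbf{c}_{t-1}$ vector. Note the latter makes the action side
  *recurrent*: it can learn multi-lag choice kernels.
* **Memory-ANN**: the module inputs are $[r_{t-1}, \mathbf{s}^{(r)}_{t-1}]$
  and $[a_{t-1}, \mathbf{s}^{(a)}_{t-1}]$, where the memory states are the
  modules' own previous hidden-layer activations; the dependence on
  $Q_{t-1}(a)$ is removed. Reward processing never sees actions and vice
  versa — an architectural constraint the tests assert directly.
* **Vanilla RNN**: one recurrent tanh layer over
  $[\mathrm{onehot}(a_{t-1}),\ r_{t-1},\ \mathbf{s}_{t-1}]$ with a linear
  read-out of four logits.

Initial conditions (the source is silent): memory states start at zero, the
value vector at $Q_{\mathrm{init}}$, perseveration at zero. Trial 1 is
included in the loss. For the Vanilla RNN the first step runs with the
all-zero one-hot and mid-scale reward 0.5, so the network can learn a
first-trial bias; for the two-module and tabular models the action input
is the raw scalar $a_{t-1}$ (input width 1, following the architecture
definition), where an "all-zero" encoding would collide with arm 0 — those
modules therefore simply do not run before the first observed trial, and
trial 1 is predicted from the initial state (a uniform prediction, since
all logits are equal). This makes trial 1 a constant loss term for those
models and a learnable one for the RNN; with 150-trial blocks the
difference is negligible.

## Fitting

Everything is behavioural cloning: the negative log-likelihood of the
observed choices, $L = -\sum \log p(a_t)$, summed over blocks and valid
trials. Missed trials contribute no loss and freeze all latent state.
Losses convert to trial-wise prediction accuracy via
$\mathrm{acc} = 100\,e^{-L/n}$ with $n$ the trial count behind $L$ — the
geometric-mean probability assigned to the observed choices; chance is
exactly 25%. Per-block accuracies use each block's own valid-trial count.

Neural models train with Adam (implemented in the package) on batches of
blocks sampled with replacement, with decoupled L2 weight decay on the
weight matrices (not on biases or on the forgetting/initial-value scalars,
which have priors of their own in the architecture) and checkpoint
selection by validation loss. Gradients are exact backpropagation through
time, hand-derived per architecture and implemented in C++; the test suite
checks every architecture's gradient against central finite differences
(relative error ~1e-8) and every forward pass against a plain-R oracle
through the step interface.

Tabular variants are fitted by multi-start L-BFGS-B over the raw
(transformed) parameters on the same C++ likelihood. This deviates from
the original protocol, which trained everything with the same stochastic
optimizer; with at most eight free parameters the quasi-Newton fit reaches
the same optimum deterministically and in seconds, which matters for a
test suite that refits models many times. Nesting (Best RL never fits
worse than Simple RL on shared data) is asserted in the tests.

Desk-scale defaults: hidden size 12, batch 16, step size 2e-3, 12,000
steps, validation every 300 steps, 2 sweep replicates. The full-scale
preset (`training_config(full_scale = TRUE)`: hidden 32, batch 32, up to
1e6 steps) is recorded but never a default. Problem sizes throughout
(cohorts of 100-200 participants, 2-3 blocks each) were chosen so the full
analysis replays in well under an hour on a single CPU while keeping every
qualitative contrast statistically decisive; they are a deliberate
reduction of the original corpus (862 participants, 4,134 blocks).

## Synthetic cohorts

`build_dataset()` draws one agent per participant, simulates each block
open-loop on a fresh reward schedule (per participant *and* per block, as
in the original design), and assigns whole participants to
train/validation/test splits (80/10/10 by default) by seeded permutation —
no participant's blocks ever straddle splits.

The default generator is a heterogeneous Best-RL population. The original
study fits a single population-level model and never parameterises
individual differences, so the priors here are package decisions, chosen
to produce clearly above-chance, visibly perseverative learners on the
scaled reward axis: $\alpha \sim \mathrm{Beta}(6,14)$ (mean 0.3),
$\beta \sim \mathrm{Gamma}(25, 2.5)$ (mean 10 — value differences are a
few tenths on the scaled axis, so this corresponds to moderately
deterministic choice), $\kappa \sim U(0, 0.25)$, $f \sim \mathrm{Beta}(2,18)$,
$b \sim U(-0.03, 0.03)$, $Q_{\mathrm{init}} \sim N(0.5, 0.08)$.

### The rich-memory teacher

To exercise the model-comparison ordering, the package ships a
hand-constructed generator in the Memory-ANN architecture class rather
than a trained network (deterministic, fast, and its mechanisms are known
exactly). Its three mechanisms each target one rung of the ladder:

1. *Drifting reward reference.* The value written to the chosen arm is
   $Q(a) = 0.5 + g\,(r - m)$ with $m$ an exponential trace of obtained
   rewards (rate 0.08) and gain $g = 1$. The update ignores the arm's
   previous value. With $g = 1$ the *static* part of the map
   ($Q \approx r + \mathrm{const}$) is exactly expressible by the biased
   delta rule at $\alpha \to 1$, so Best RL and RL-ANN sit at the same
   rung; only the drift of $m$ is memory-specific.
2. *Multi-lag choice kernel.* $ck \leftarrow \rho\,ck +
   (1-\rho)\,\mathrm{onehot}(a)$ with $\rho = 0.75$, contributing
   $0.35\,ck$ to the logits. A single-lag perseveration term (Best RL,
   RL-ANN) can only approximate it; Context-ANN's recurrent $c$ input can
   express it.
3. *Within-block sharpening.* The softmax inverse temperature ramps from 4
   to 10 across the 150 trials (exploration early, exploitation late).
   Time-on-task is in no model's inputs, but a recurrent memory state can
   integrate a trial counter — this separates Memory-ANN from
   Context-ANN.

Under the shared desk-scale protocol the held-out accuracies order as
Memory-ANN > Context-ANN > RL-ANN ≈ Best RL, each inequality a significant
paired t-test over test blocks (the acceptance test computes these).

### Model recovery and individual differences

The complementary check — on data generated *by* Best RL, Best RL is not
beaten by Memory-ANN — holds only when the generator is a *single* agent
(point-mass prior). With a heterogeneous Best-RL cohort the flexible
network genuinely beats the population-level Best RL fit, because its
recurrent state infers each participant's parameters from their history:
flexible sequence models capture individual differences implicitly even
when no one models them. The package therefore runs recovery checks on
single-agent cohorts and keeps the heterogeneous prior for behavioural
studies; users comparing flexible and rigid models on heterogeneous data
should be aware that part of any flexibility advantage can be
between-participant variance.

## Behavioural battery

Decisions where the original description is silent:

* Stay-probability curves bin reward change at 10 points (configurable).
* Repeat streaks include runs of length 1 — required for the chance value
  of $4/3 \approx 1.3$ (geometric run lengths at $p = 3/4$) to emerge.
* Cyclic responses use overlapping windows of four consecutive valid
  trials containing each action once; the iid-uniform expectation is
  $147 \cdot 4!/4^4 \approx 13.8$ per 150-trial block.
* LZW "length" is the emitted-code count; the compressibility ratio
  divides the mean code count of 100 matched iid-uniform sequences by the
  observed sequence's count. Compression and decompression round-trip
  exactly (property-tested), including the classic self-referential
  dictionary case.
* The lagged regression (20 bandit-reward and 20 other-reward regressors,
  fitted per bandit and averaged) uses a small ridge penalty
  ($\lambda = 10^{-3}$ via glmnet, unstandardised) against perfect
  separation in rarely-chosen bandits, zero-padding before the block
  start, and drops rows whose target trial was missed. Recovery of known
  kernels (geometric decay, pure lag-1 repetition, null) is tested
  against constructed generators.
* Missed trials: metrics operate on the valid-trial subsequence; runs and
  windows are computed after dropping missed trials (miss rates in the
  emulated design are a fraction of a percent, so bridging vs breaking
  runs is immaterial).

## Interpretability conventions

Teacher forcing records the latent state *going into* each trial, so row
$t$ aligns with the policy that predicted choice $t$. PCA of pooled memory
states is mean-centred and unscaled; each component's sign is fixed so its
score correlates non-negatively with the previous trial's reward, giving
"PC1 = reward sensitivity" a reproducible orientation (no convention is
stated in the source). Probe grids default to 21 reward points crossed
with 11 state samples within ±1.5 SD along a PC; for value-conditioned
architectures the state axis is the previous value between the 10% and
90% quantiles of closed-loop values (the source states both 10-90% and
5-95% in different places; the Methods value is used). Priming and
activity-injection operate on a fresh reward module from the zero state;
injection adds a multiple of a PC vector to the running state at a chosen
trial and reports the paired difference of value trajectories. By default
analyses keep all PCs with at least 1% explained variance.

## Numerical notes and limitations

Softmax is computed with max-subtraction everywhere (logit-shift
invariance is asserted). The likelihood kernels treat an invalid trial as
a total pass-through in both the forward pass and the adjoint, which the
gradient checks cover explicitly. Weight serialisation uses JSON at 17
significant digits — round trips are exact to ~1e-15 relative error, not
bit-exact.

What passing tests do and do not show: the synthetic cohorts emulate the
*structure* of the human corpus (cohort shape, per-block schedules,
participant-level splits, missed trials) and known mechanism classes, not
human behaviour itself. Reaction times, education covariates, slow
non-stationarities across blocks, and any mechanism outside the
implemented generator families are absent; the headline human fit
percentages are therefore not reproduced here, only the ordering and
chance-level anchors that are properties of the method rather than of the
human sample. Results on real data require the original corpus in the
package's block format.
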