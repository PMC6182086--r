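---
title: "Localized synaptic change in recurrent network models of prefrontal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized synaptic change in recurrent network models of prefrontal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plasticrnn)
```

## The question this package addresses

Recurrent neural networks (RNNs) trained on the context-dependent
integration task -- choose left or right from noisy motion *and* color
evidence, where a contextual cue decides which modality is relevant on the
current trial -- are a standard model of prefrontal cortex (PFC) function.
Four model families with very different learning rules can all solve the
task:

* **HF**: a tanh rate network trained on a quadratic objective that scores a
  scalar readout at the first and last time points of each trial (the family
  historically trained with Hessian-free optimization);
* **pycog**: a rectified-linear rate network obeying Dale's law (separate
  excitatory and inhibitory populations, 4:1) trained by masked-error
  stochastic gradient descent;
* **pyrl**: an actor-critic pair of gated recurrent networks trained with the
  REINFORCE policy-gradient estimator plus a learned reward baseline;
* **rHebb**: a tanh network trained by node perturbation -- a
  reward-modulated Hebbian rule with a superlinear eligibility trace and no
  gradient information at all.

The package trains all four families, then asks *where* learning changed the
recurrent synapses. The central statistic is the **post-mean weight change**
of unit $i$,

$$\bar W^{\mathrm{diff}}_i \;=\; \frac{1}{N}\sum_j \lvert W^{\mathrm{last}}_{ij}
- W^{\mathrm{init}}_{ij}\rvert ,$$

the mean absolute change of unit $i$'s incoming synapses. A strongly
right-skewed distribution of $\bar W^{\mathrm{diff}}$ over units means
learning concentrated its changes on a small subpopulation of postsynaptic
neurons. Distribution shape is quantified by the Shapiro-Wilk test, the
D'Agostino skewness Z-test and the Anscombe-Glynn kurtosis Z-test (excess
kurtosis, normal $=0$), computed by `dist_stats()` exactly as in the
reference SciPy implementations. The behavioral relevance of the
high-plasticity units is probed by rank-ordered inactivation sweeps
(`run_inactivation_sweep()`): units are clamped cumulatively in descending,
ascending or shuffled order of $\bar W^{\mathrm{diff}}$ while task accuracy
is measured, and the orders are compared with a two-way ANOVA and Tukey HSD
post-hoc tests.

## The task and its parameterization

A trial is `trial_duration / dt` steps of piecewise-constant sensory offsets
(the signed coherences $d_m$, $d_c$) plus iid Gaussian noise, with two
binary context lines of which exactly one is active. Two encodings exist:
the signed two-channel form (HF, rHebb) and a separated four-channel
nonnegative form (pycog, pyrl; channel order motion-right, motion-left,
color-red, color-green, value `baseline + |d|` on the favored channel). The
correct choice is the sign of the context-relevant coherence; trials with
zero relevant coherence are rejected by default because their correct answer
is undefined.

Only a few task constants are fixed by the reference configurations (HF:
30 ms trials, sensory noise sd 0.04, state noise sd 0.004). The remaining
scales are package conventions, chosen once per family to match each
reference implementation's input regime and then left alone:

| family | encoding | coherence levels | sensory sd | steps |
|--------|----------|------------------|-----------|-------|
| hf | signed 2-channel | ±0.01, ±0.02, ±0.04 | 0.04 | 30 |
| pycog | separated 4-channel (baseline 0.2) | ±0.02, ±0.04, ±0.08 | 0.04 | 50 |
| pyrl | separated 4-channel (baseline 0.5) | ±0.1, ±0.2, ±0.4 | 0.2 | 30 |
| rhebb | signed 2-channel | ±0.125, ±0.25, ±0.5 | 0.25 | 50 |

Six symmetric coherence levels per modality support psychometric curves; the
magnitudes keep the per-step signal-to-noise ratios of the three graded
levels identical across families (0.25, 0.5, 1). The pyrl family uses
order-one input amplitudes and short trials because its only learning signal
is a single terminal reward: with 0.04-scale inputs and 50-step trials the
likelihood-ratio estimator does not escape the context-blind strategy
(integrate both modalities, ~75% correct) in any reasonable budget.

## Dynamics and discretization

The leaky rate dynamics are integrated by explicit first-order Euler,
$x_{t} = (1-\alpha)x_{t-1} + \alpha(W_{rec} r_{t-1} + W_{in} u_t + b_x +
\rho_t)$ with $\alpha = dt/\tau$ ($\tau = 10$ ms, $dt = 1$ ms), rates
$r = \tanh(x)$ (HF, rHebb) or $r = \max(x, 0)$ (pycog, pyrl), and readout
$z = W_{out} r + b_z$. Noise is added per step at the stated standard
deviations without $\sqrt{dt}$ rescaling, matching the discrete-time
convention of the source scripts. The pyrl families use gated units: update
and reset gates $q, s$ are logistic readouts of the input and previous
rates, the candidate drive is $W_{rec}(s \circ r) + W_{in}u + b_x$, and
$x_t = (1-q)\circ x_{t-1} + q \circ \text{candidate}$; with both gates
pinned at 1 this reduces to an unleaky recurrent step. The gate equations
are stated here as the package's convention since the reference text does
not restate them.

Choices are decoded at the final decision window: sign of the scalar output
(HF), sign of the designated output unit's rate (rHebb, unit 1 by default;
"an arbitrary unit" in the reference), or argmax over output channels
(pycog: 2 channels; pyrl: choice 1 / choice 2 / stay). Exact argmax ties
break toward the lowest channel index and are flagged.

Inactivation clamps unit outputs to zero at every recurrent step
(pycog/pyrl/rhebb) or pins the membrane potential at the unit's bias (HF),
applied inside the loop so lesioned units neither compute nor transmit.

## Trainers and their design decisions

**HF.** The objective is the mean over trials of half the squared readout
error at $t = 0$ (target 0) and $t = T$ (target ±1). The optimizer is
adaptive-moment gradient descent (Adam) on backpropagation-through-time
gradients with global norm clipping -- a deliberate, documented deviation:
the model is defined by its objective, not by the second-order solver, and
the curvature/conjugate-gradient machinery (with Levenberg-Marquardt
damping adaptation) is out of scope. Structural damping is available as an
optional penalty (cross-entropy between the current rate trajectory and a
frozen reference) but is off by default. At reduced scale the package
initializes HF weights from the comparable-initialization setting (Gaussian
sd 0.15) rather than sd 0.01: the tiny initialization leaves the network in
its linear regime, where no first-order method finds the multiplicative
context gating and training stalls at the context-blind 75% plateau. The
reference study itself ran this alternative initialization and reported
comparable weight-change results.

**pycog.** Masked mean-squared error $L_n = \frac{1}{N_{out} T} \sum_{s,t}
M_t (z - z^{target})^2$ (the mask selects the final decision window), plus
$\lambda_\Omega$ times the vanishing-gradient regularizer. The regularizer
penalizes decay of the backpropagated error norm between consecutive steps;
its gradient uses the standard constant-delta approximation and flows into
the recurrent matrix only. $\lambda_\Omega$ defaults to 0.01 (the reference
does not print a value). After every update the Dale constraint is
re-projected: entries of excitatory columns that became negative (and of
inhibitory columns that became positive) are clipped to zero, and the
diagonal stays zero. The projection is idempotent and enforced as an
invariant in the tests.

**pyrl.** The policy samples one of three actions from the softmax readout
at the decision step. The gradient estimator is
$(R - v)\,\nabla \log \pi(a)$, where $v$ is the baseline network's
cumulative-reward prediction; the baseline receives the policy's rates and
action probabilities (input width $N_{rec} + N_{out}$, 103 at reference
scale) and minimizes the mean squared error of its return prediction over
all steps. Rewards: +1 correct, 0 incorrect; fixation-break penalties exist
in the reward schedule but no fixation epoch is configured by default. A
small entropy bonus (0.01) on the decision-step policy prevents premature
collapse onto a single action -- a standard REINFORCE stabilizer, noted
here because the reference does not use one. Exactly 10% of each network's
recurrent synapses are plastic (a fixed random mask); all other recurrent
entries are bit-identical between the initial and final snapshots, which
the tests assert exactly.

**rHebb.** Node perturbation with the superlinear eligibility trace
$e_{ij}(t) = e_{ij}(t-1) + S\!\big(r_j(t-1)\,(x_i(t) - \bar x_i)\big)$,
$S(x) = x^3$, and end-of-trial update $\Delta W = \eta\, e\, (R - \bar R)$,
where $R$ is the negative mean absolute deviation of the output unit from
the optimal response over the decision window. Three units are clamped as
constant-drive inputs; they and the output unit are excluded from the
weight-change analysis (196 of 200 units at reference scale). Conventions
and desk-scale stabilizers, all configurable in `rhebb_config()`:

* exploration is sparse per-unit kicks (rate 0.03 per unit-step, amplitude
  uniform ±8 entering the drive) on top of weak Gaussian state noise,
  following the node-perturbation scheme of the source implementation;
* the running average $\bar x$ is fast (5 ms), so the eligibility trace
  responds to kick-induced fluctuations rather than slow stimulus drift;
* the reward baseline $\bar R$ is a per-condition running mean keyed on the
  full (context, $d_m$, $d_c$) triple. Coarser conditioning (signs only)
  leaves systematic within-condition reward variance that correlates with
  stimulus-locked eligibility and drives a destructive weight drift;
* each trial's update is clipped elementwise at `max_dw` (5e-4): the cubed
  trace is heavy-tailed and single trials can otherwise move weights by
  multiples of their initial scale;
* the recurrent matrix relaxes toward its initial state at 1e-3 per trial.
  Without this, the reward-noise component of the updates accumulates as an
  unbounded random walk that eventually destroys the network's dynamics
  (training curves rise and then collapse to chance); with it the walk is a
  bounded Ornstein-Uhlenbeck fluctuation while consistent reward
  correlations still integrate to large changes;
* because node-perturbation progress is non-monotone, `W_last` is the
  parameter snapshot at the best validation checkpoint (validation runs
  with exploration off), not the final iterate.

## Weight-change analysis

`summarize_model()` applies the family's analysis mask (`all` for HF,
excitatory-to-excitatory for pycog, plastic-synapses-only for pyrl, output
and constant-input units excluded for rHebb), forms $W^{diff} = W^{last} -
W^{init}$, computes the post-mean vectors of $|W^{last}|$ and $|W^{diff}|$,
ranks units by the latter, and runs `dist_stats()` at both the unit level
(post-mean values) and the synapse level (masked $W^{diff}$ entries
flattened; 10,000 elements for HF, 14,400 for pycog E-E, 1,000 for pyrl,
38,416 for rHebb at reference sizes). For the pyrl family the post-mean
divides by the number of analyzed (plastic) presynaptic entries of each row
rather than by $N_{rec}$ -- a flagged interpretation: it is the mean over
the analyzed population, and with the reference definition the two differ
only by the constant factor 10.

Skewness and kurtosis use the biased moment-ratio estimators ($g_1$,
$g_2 = m_4/m_2^2 - 3$), matching the reference statistics; the Shapiro-Wilk
statistic is computed on the first 5,000 values when a synapse-level sample
exceeds the test's implementation limit.

## Perturbation experiments

`run_inactivation_sweep()` lesions each trained replicate cumulatively in
increments of 10 units per the three sort orders, measuring accuracy on 200
fresh trials per cell; evaluation batches are shared across sort orders
(paired design), so the full lesion of the rankable population is exactly
order-independent. For pycog only excitatory units are lesioned (the
analysis and ranking cover the E-E subnetwork); for rHebb the grid is
truncated at 100 at reference scale. `two_way_anova()` fits the
fixed-effects accuracy ~ n_inact x sort_type model whose degrees of freedom
are pure functions of the design -- (10 levels x 3 orders x 11 systems)
gives error df 300, (12 x 3 x 11) gives 360, (10 x 3 x 20) gives 570 --
and `posthoc_pairwise()` runs Tukey HSD per lesion size.
`run_size_sweep()` retrains across network sizes (five seeds per size) and
compares accuracy and post-mean-change skewness across sizes with
Kruskal-Wallis and Dunn tests (the Dunn statistics are computed from the
tie-corrected rank-sum formula since no installed package provides them).

## Synthetic fixtures

`make_planted_fixture()` generates weight-change matrices with `k` planted
high-plasticity postsynaptic rows (Gaussian rows with sd `sigma_hot` against
a `sigma_bg` background) so the entire analysis stack can be validated
without training: ranking must recover the planted rows (>= 99% of seeds at
contrast 10), the post-mean-change distribution must be significantly
right-skewed, and null fixtures (`k = 0`) must keep the skew test at its
nominal level. The fixtures emulate only the weight structure -- not
temporal activity, not the correlation between plasticity and behavioral
relevance -- so passing them validates the analysis pipeline, not the
training claims.

## Desk-scale study conditions

The test suite and the reproduction script run reduced-scale instances
(`scaled_defaults()`): HF at 64 recurrent units, pycog and pyrl at 80
(baseline 40), rHebb at 64, with training budgets of a few thousand
iterations (rHebb: 24,000 trials; 10,000 in the test suite, whose pyrl runs
instead train to convergence, the regime in which that family's plasticity
is concentrated enough for the lesion contrast to be measurable). Sizes were
chosen so that the post-mean samples keep the skewness test reasonably
powered (the reference analyses use 100-196 units; below ~50 units the test
has little power against the skew magnitudes actually observed) while one
full training run stays in the seconds-to-minutes range on one CPU. The
gradient families stop at 0.95 validation accuracy rather than at the bare
0.85 bar: the reference systems train to convergence, and the localization
phenomena live in the well-trained regime -- a network stopped the moment
it scrapes past the minimal criterion has accumulated only diffuse, weak
changes, which blunts both the post-mean skew and the rank-ordered lesion
contrast. The margin also keeps fresh-trial accuracy clear of the bar
despite validation sampling noise.

What desk-scale results do and do not show: the gradient families learn the
task well past the 85% bar, and the headline localization phenomena
reproduce with family-dependent strength. HF reproduces everything:
strongly right-skewed post-mean changes in every seed and a decisive
rank-ordered lesion contrast (clamping the ten most plastic of 64 units
roughly halves accuracy while the ten least plastic barely matter). pyrl
shows the lesion contrast only near-total lesions (60-70 of 80 units) --
with only 10% of recurrent synapses plastic the network is extremely
lesion-robust -- and its unit-level skew test is rarely significant: each
postsynaptic unit's post-mean averages only ~8 plastic synapses, so the
per-unit statistic is noise-dominated at this scale. pycog sits in between:
a consistent ~10-point mean accuracy gap between descending and ascending
lesion orders at every lesion size that the five-replicate Tukey test is
nevertheless underpowered to certify, and significant skew in roughly half
the seeds. The exact reference statistics (tables of Z values, ANOVA F
values) are not desk-scale reproducible and are not asserted. Known limitation: the rHebb
family, trained at roughly 25-50x fewer trials and a third of the reference
network size, reaches peak validation accuracies of about 0.75-0.82 --
below the 85% bar the full-scale reference runs clear. The bottleneck is
the sample efficiency of node perturbation, not representational capacity
-- a ridge readout of the untrained 64-unit reservoir already separates the
task (the test suite verifies this) -- and not a defect of the analysis
stack (which is validated on fixtures). Equally, the desk-scale rHebb weight changes are dominated by
the clipped, dense update regime, so its post-mean skew is weaker than the
reference's and not asserted as universally significant.

## Numerical choices

Everything is reproducible from integer seeds below $2^{31}$ through a
counter-based derivation (`derive_seed()`); identical seeds give
bit-identical batches, initializations and (gradient and Hebbian backends)
training runs. Gradient-norm clipping defaults to 1. Ties in rankings break
toward the lower unit index. Distribution tests require $n \ge 8$ and
non-constant samples and fail loudly otherwise. Degenerate inputs (empty
batches after zero-coherence exclusion, all-false error masks, out-of-range
lesion indices, non-finite losses) raise immediate errors rather than
propagating.
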