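# plasticrnn

Where does learning change the synapses of a recurrent network? `plasticrnn`
trains four families of recurrent neural-network models of prefrontal cortex
on the context-dependent integration task -- choose between two options from
noisy motion and color evidence, where a per-trial contextual cue decides
which modality counts -- and analyses the *localization* of the resulting
synaptic changes.

The four families differ in architecture and, more importantly, in learning
rule:

| family | units | rule |
|--------|-------|------|
| `hf` | tanh, scalar readout | gradient descent on a quadratic objective scoring the first and last time points |
| `pycog` | rectified-linear, Dale's law (4:1 E:I) | masked-error SGD with a vanishing-gradient regularizer and sign re-projection |
| `pyrl` | gated rectified-linear actor-critic pair | REINFORCE policy gradient with a learned reward baseline; 10% plastic recurrent synapses |
| `rhebb` | tanh, readout from an arbitrary unit | reward-modulated Hebbian rule: cubed eligibility trace x reward-prediction error (node perturbation) |

The core statistic is the **post-mean weight change** of postsynaptic unit
*i*,

    Wdiff_bar[i] = mean_j | W_last[i, j] - W_init[i, j] |,

whose distribution over units is tested for normality (Shapiro-Wilk),
skewness (D'Agostino Z-test) and excess kurtosis (Anscombe-Glynn Z-test). A
right-skewed distribution means learning concentrated on a small
subpopulation of units. Rank-ordered inactivation sweeps (clamping units in
descending / ascending / shuffled order of their post-mean change while
measuring accuracy, compared by two-way ANOVA and Tukey HSD) test whether
those high-plasticity units actually carry the behavior, and network-size
sweeps (Kruskal-Wallis + Dunn) relate localization to network size.

## Worked example

Train a reduced-scale HF-family network (64 recurrent units), evaluate it on
fresh trials, and summarize where its weights changed:

```r
library(plasticrnn)

res <- train_family("hf", N_rec = 64,
                    trainer_spec = hf_spec(n_iterations = 3000), seed = 1)
batch <- make_batch(default_task_config("hf"), 500, "alternating", seed = 99)
accuracy(res$record$W_last, res$arch, batch, seed = 100)
#> [1] 0.896

summarize_model(res$record, res$arch)
#> weight_change_summary 'hf' (policy all)
#>   post units: 64, analyzed synapses: 4096
#>   post-mean change: skew 1.12 (Z = 3.40, p = 0.000663)
#>   top units by post-mean change: 29 27 6 30 22
```

The model clears the 85% performance bar on 500 held-out trials, and the
distribution of per-unit mean absolute weight changes is significantly
right-skewed: a handful of units (here 29, 27, 6, ...) absorbed most of the
learning. `run_inactivation_sweep()` on a list of such records, followed by
`two_way_anova()` and `posthoc_pairwise()`, then shows that clamping those
high-plasticity units first degrades accuracy faster than clamping
low-plasticity units first.

The same interface drives every family (`train_family("pycog", ...)`,
`"pyrl"`, `"rhebb"`), and `run_pipeline()` executes train -> analyze ->
inactivate from a YAML configuration with a manifest of seeds and checksums.
See the methods vignette (`vignettes/weight-change-localization.Rmd`) for
the models, the task parameterization, and every numerical design decision,
including the known desk-scale limitation of the rHebb family.

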