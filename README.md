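# predcortex

Rate-based simulation of the neocortical L4 – L2/3 – L5 microcircuit
learning by **temporal self-supervision**: layer 2/3, driven by delayed
sensory input relayed through L4 and by top-down context, learns to predict
the layer-5 encoding of the input that is arriving *now* through the direct
thalamic pathway. The mismatch between prediction and encoding is the only
teaching signal — no labels anywhere.

The package is for computational neuroscientists who want to simulate and
probe this circuit: its forward dynamics with knockout switches, its
plasticity rules with reconstruction-gradient blocking and
symmetric/random/absent error feedback, the synthetic tasks that exercise
it (contextual Gabor sequences; visuomotor speed/flow streams with
mismatch halts), and the analysis battery used to characterize it (linear
decoding, PCA profiles, Treves–Rolls population sparseness, per-neuron
mismatch errors with baseline subtraction, simulated stimulation, and a
denoising-autoencoder reference).

## The model in brief

With `σ` the logistic sigmoid,

    z4[t]  = σ(W_thal_l4 · x[t-1])                        (delayed route)
    z23[t] = σ(W_l4_l23 · z4[t] + W_td_l23 · i_td[t])     (context joins here)
    z5[t]  = σ(α · W_l23_l5 · z23[t] + W_thal_l5 · x[t])  (direct route, α = 0.3)

L2/3's output is the raw prediction `ẑ5 = W_l23_l5 · z23`, trained by

    C_total = λ_p · ½‖ẑ5 − z5‖² + λ_r · ½‖x_t − W_decoder · z5‖²

where the second, reconstruction term applies to L5 only and prevents
representational collapse. Its gradient is *blocked* from every
L2/3-upstream weight, and the predictive error reaches L2/3 through an
explicit feedback matrix — the transpose of `W_l23_l5`, a fixed random
matrix (feedback alignment), or nothing. All updates are online, one per
timestep, validated against central finite differences in the test suite.

## Worked example

Train the circuit on the contextual Gabor task (orientation on an
18°-spaced grid, a three-valued rotation cue as top-down context) at a
reduced desk scale, then decode from each layer:

```r
library(predcortex)

cfg <- gabor_config(n_l4 = 64, n_l23 = 64, n_l5 = 64,
                    train_steps = 20000, eval_steps = 2000)
model <- train_gabor_model(seed = 1, cfg)
ev <- eval_gabor_model(model)

# what orientation is arriving at L5? ask the L2/3 prediction vector:
decode_layer(ev$fwd, ev$stream, layer = "l23", target = "current", seed = 1)
#> <decode_result> accuracy = 0.896 (1595 train / 405 test, multinom)

# and ask L5 itself:
decode_layer(ev$fwd, ev$stream, layer = "l5", target = "current", seed = 1)
#> <decode_result> accuracy = 0.956 (1595 train / 405 test, multinom)

# empirical chance via label shuffling (10 orientation classes):
decode_layer(ev$fwd, ev$stream, layer = "l5", target = "current",
             seed = 1, shuffle = TRUE)
#> <decode_result> accuracy = 0.089 (1595 train / 405 test, multinom, shuffled labels)

sparseness_trial(ev$fwd$z_l23, layer = "L2/3")
#> <sparseness_result> L2/3: S = 0.677 (N = 64, 2000 stimuli)
sparseness_trial(ev$fwd$z_l5, layer = "L5")
#> <sparseness_result> L5: S = 0.865 (N = 64, 2000 stimuli)
```

The L2/3 prediction decodes the *upcoming* stimulus at ~90% because its
only inputs are the previous frame and the rotation cue; L5 decodes the
current stimulus it receives directly. The Treves–Rolls ratio `S` is lower
in L2/3 than in L5: the predictive layer is the sparser one. The
L2/3→L5 learning rule itself shows a depression-to-potentiation switch
with increasing postsynaptic activity:

```r
plasticity_curve(n_samples = 500, seed = 1)$slope
#> 0.472   # > 0: depression at low L5 activity, potentiation at high
```

Named experiments (`run_experiment("ablation")`,
`"feedback_sweep"`, `"sparsity"`, `"mismatch"`, ...) reproduce the
knockout, feedback-regime, sparseness and visuomotor-mismatch analyses
with mean ± s.e.m. aggregation over five initial conditions; a thin CLI
wrapper lives in `inst/scripts/run_experiment.R`.

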