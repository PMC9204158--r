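# emgrasp

Decoding the **upcoming grasp gesture** from multichannel surface EMG
during natural reach-to-grasp movements — and measuring *how early* the
decision is available.

When a hand reaches for an object, forearm and hand muscles pre-shape the
grasp before contact. `emgrasp` implements the full decoding chain that
exploits this for robotic-hand pre-shaping:

1. **Synthetic sessions** (`generate_session`): a protocol-faithful
   generator — 13 grasp gestures × 4 objects × 6 four-second trials, 12
   channels at 1562.5 Hz, per-phase amplitude-modulated zero-mean Gaussian
   carriers, MVC recordings — with complete ground truth, so every stage
   is testable without human recordings.
2. **Preprocessing** (`emg_bandpass`, `emg_envelope`, `mvc_normalize`):
   zero-phase 40–500 Hz Butterworth band-pass, linear envelopes, and
   per-muscle normalization by maximum-voluntary-contraction envelopes.
3. **Unsupervised phase segmentation** (`ggs_fit`): greedy Gaussian
   segmentation places K = 3 breakpoints maximizing
   `sum_k -(n_k/2) log det(Sigma_k + lambda tr(Sigma_k)/d I)`, splitting
   each trial into reaching / grasping / returning / resting; an exact
   dynamic-programming oracle (`exhaustive_fit`) verifies the greedy
   solution on small instances.
4. **Windowed features** (`featurize_session`): 320-ms windows every
   40 ms; per channel RMS, MAV and variance, giving 36-dimensional
   feature vectors.
5. **Gesture classifier** (`train_gesture_model`): 50 extremely
   randomized trees over 14 classes (rest + 13 gestures), trained under
   three phase-selection strategies — S1 reaching+resting, S2
   grasping+resting, S3 reaching+grasping+resting — with a per-object
   4/2-trial, 3-fold validation plan.
6. **Grasp-onset-aligned evaluation** (`evaluate_strategy`): validation
   trials aligned at grasp onset (t = 0), 700 ms of preceding rest
   prepended, probability/accuracy curves averaged across trials; the
   **intersection time `t_i`** (when the grasp-gesture probability
   overtakes rest — negative means before grasp onset) and the
   **probability margin `d_p`** (grasp-probability peak minus the top
   competitor) summarize each strategy.

See `vignettes/decoding-grasp-intent.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(emgrasp)

# reduced session: 13 gestures x 1 object x 6 trials
run <- run_pipeline(protocol_config(objects_per_gesture = 1, seed = 1),
                    split_seed = 7, model_seed = 11)
print(run)
#> <pipeline_run> 78 trials, median breakpoint error 34.9 ms
#> <strategy_evaluation> S1: t_i = -1957 ms, d_p = 0.890 (78 trials)
#>   accuracy: reaching 0.99, grasping 0.78, returning 0.24, resting 1.00
#> <strategy_evaluation> S2: t_i = -1129 ms, d_p = 0.811 (78 trials)
#>   accuracy: reaching 0.92, grasping 0.92, returning 0.54, resting 1.00
#> <strategy_evaluation> S3: t_i = -1957 ms, d_p = 0.934 (78 trials)
#>   accuracy: reaching 1.00, grasping 0.94, returning 0.56, resting 1.00
```

Reading the output: the segmentation recovers the hidden phase
boundaries to ~35 ms (median). The reach-trained model S1 detects the
coming gesture early (its probability curve overtakes rest almost 2 s
before grasp onset), the grasp-trained model S2 commits ~800 ms later,
and the combined strategy S3 is both early *and* has the widest margin
`d_p` over its strongest competitor gesture — the pattern that motivates
training on the full reach-and-grasp dynamics. Returning-phase accuracy
is low by construction: no strategy trains on that phase.

Stage-level functions (`generate_session`, `preprocess_session`,
`segment_session`, `featurize_session`, `build_split`,
`evaluate_strategy`) expose every intermediate; a thin command-line
wrapper lives in `inst/scripts/emgrasp-pipeline.R`.

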