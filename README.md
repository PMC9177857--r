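# olfrl

Analysis toolkit for head-fixed mouse olfactory reward-learning
experiments: a trial-based temporal-difference model of reward prediction,
learning-rate estimation from pupillometry, lick-based behavioral metrics,
tetrode spike preprocessing, population and single-unit coding analyses,
and a miniature event-related BOLD GLM with beta-series connectivity — all
exercisable on a bundled synthetic-data generator, so every stage is
testable without experimental data.

## The paradigm and the model

Mice learn a go/no-go odor task in which three conditioned stimuli predict
a water reward with probability 1.0 (CS100), 0.5 (CS50) and 0.0 (CS0).
Each trial is 1 s of odor, a 1.7 s wait, and the outcome (US) 2.7 s after
odor onset; trial onsets are jittered uniformly between 10 and 12 s, cue
proportions are equal, and no cue or reward repeats more than three times
in a row.

Learning is modeled with a trial-based TD(0) rule over three within-trial
timepoints (baseline *t* = 0, odor *t* = 1, outcome *t* = 2). Each state
*s<sub>t</sub>* carries a value *V*(*s<sub>t</sub>*) (the reward
prediction); the prediction error compares successive predictions,

> δ<sub>t</sub> = r<sub>t</sub> + V(s<sub>t</sub>) − V(s<sub>t−1</sub>),
> &emsp; V(s<sub>t−1</sub>) ← V(s<sub>t−1</sub>) + α·δ<sub>t</sub>,

with binary reward r<sub>2</sub> ∈ {0, 1}, V(s<sub>2</sub>) ≡ 0, and
learning rate α. At the outcome the error reduces to δ<sub>2</sub> =
r − V(CS): maximal for surprising CS50 rewards, zero for fully predicted
ones. The learning rate is a free parameter estimated from pupillometry:
per-trial pupil dilation (percent change from the −2..0 s baseline) is
modeled as a linear combination of current and past state values and
absolute prediction errors, d(t) = Σ<sub>τ</sub> a<sub>τ</sub>
V(s<sub>t−τ</sub>) + Σ<sub>τ</sub> b<sub>τ</sub> |δ(t−τ)|, and α is found
by least squares (grid over α, exact linear solve for a, b).

Downstream analyses implement the study chain: anticipatory-lick
classification (≥3 licks in the 1.5–2.8 s or 2.8–4.1 s window) and session
performance; Poisson regression of CS50 anticipatory licking on the ±1-coded
outcomes of the six previous CS50 (outcome history) or CS100/CS0 (satiety)
trials; spike detection at 7.5× the median absolute deviation after median
subtraction and 300–5000 Hz band-pass filtering; population-vector
deviation from baseline, cross-cue correlation and time-embedded
trajectories; sliding-window auROC response profiles with hierarchical
clustering into transient / ramping / inhibited / sustained groups;
monotonic reward-probability and cue-dominance tests, reward surprise,
outcome discrimination and ordering chance levels; and an event-related
GLM (stick events convolved with a fast, unit-peak gamma HRF) with
parametric modulators, group one-sample *t* maps thresholded at FDR
*q* = 0.025 per tail, percent signal change, frame-wise displacement, and
per-trial beta-series functional connectivity.

## Worked example

```r
library(olfrl)

cfg  <- task_config(n_trials = 150)              # training-style session
seq  <- generate_trial_sequence(cfg, seed = 42)
td   <- run_td_session(seq, alpha = 0.28, init = "zeros")

late <- function(ty) mean(td$v_cs[which(td$cs == ty)[34:50]])
sprintf("late V: CS100 %.3f  CS50 %.3f  CS0 %.3f",
        late("CS100"), late("CS50"), late("CS0"))
#> "late V: CS100 1.000  CS50 0.470  CS0 0.000"

licks <- simulate_agent_behavior(seq, td, seed = 42)
beh   <- classify_session(licks, seq)
session_performance(beh)
#> 96
table(beh$class)
#> CorrectRejection   Hit   Miss
#>               50    94      6

round(split_by_history(td)$mean_v, 3)
#>     R     N
#> 0.589 0.336

sim <- simulate_pupil(seq, td, a = c(1, 2, 0.5), b = c(3, 1),
                      noise_sd = 0.5, seed = 42)
fit_pupil_model(list(list(seq = seq, d = sim$windows)))$alpha
#> 0.285
```

Over the final third of the session the learned values sit at the
programmed reward probabilities (1, ~0.5, 0); the synthetic agent clears
the 80% performance criterion; CS50 value is higher after a rewarded than
an unrewarded previous CS50 trial (the outcome-history signal); and the
generative learning rate 0.28 is recovered from the noisy pupil windows.

## Package layout

| Area | Key functions |
| --- | --- |
| Task / synthetic data | `task_config`, `generate_trial_sequence`, `simulate_agent_behavior`, `simulate_pupil`, `simulate_population`, `simulate_voltage`, `simulate_bold` |
| TD model | `td_step`, `run_td_session`, `simulate_td_sessions`, `split_by_history` |
| Pupillometry | `preprocess_pupil`, `window_average`, `pupil_forward`, `fit_pupil_model` |
| Behavior | `classify_trial`, `session_performance`, `anticipatory_rate`, `poisson_history_regression` |
| Ephys preprocessing | `median_subtract`, `bandpass_filter`, `detect_spikes`, `unit_qc` |
| Population coding | `build_population_vectors`, `pair_average`, `distance_from_baseline`, `cross_type_correlation`, `embed_trajectories` |
| Unit classification | `auroc_profile`, `cluster_units`, `test_monotonic_rp`, `distributed_coding_test`, `test_reward_surprise`, `test_outcome_discrimination`, `chance_level_monotonic`, `history_satiety_effects` |
| fMRI GLM | `mouse_hrf`, `build_design`, `fit_glm`, `group_stats`, `intersect_maps`, `percent_signal_change`, `framewise_displacement`, `beta_series_connectivity` |

See the methods vignette (`vignettes/olfrl-methods.Rmd`) for the modeling
assumptions, parameter choices and known limitations.
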