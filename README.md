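# gaitevents

Automated heel-strike (HS) and toe-off (TO) detection for treadmill
walking, built for the hard case: subjects walking with lower-limb
exoskeletons, where foot drag and strikes landing on the wrong force plate
routinely defeat the conventional detector (thresholding the vertical
ground reaction force at 1% of body weight).

The core method trains one single-layer LSTM regressor per input signal —
ipsilateral vertical GRF, ipsilateral heel-marker height, optionally
contralateral GRF — to map the signal to per-sample *confidence curves*:
zero between events, with a Gaussian bump of peak 1 and σ = 53.3 ms at
each event.  The per-signal predictions are fused by a signed-power
product,

    C = sign(C_iGRF)·|C_iGRF|^a · sign(C_cGRF)·|C_cGRF|^b · sign(C_iHeel)·|C_iHeel|^c,

with shipped weights (a, b, c) = (0.3, 0, 0.01) (an exponent of 0 replaces
its term by 1), and events are decoded as curve peaks of height ≥ 0.3
separated by ≥ 1000 ms.  Networks are trained *incrementally* — left side
of the cleanest trial, then its right side, then the next trial — with a
learning rate that halves every 50 epochs within each increment.

The package also provides:

* the GRF threshold baseline (`detect_threshold_events()`), faithfully
  reproducing its artifact-induced extra events;
* preprocessing (`preprocess_trial()`): zero-phase 20 Hz Butterworth
  filtering of GRF, quintic-type smoothing and linear upsampling of marker
  channels;
* the evaluation suite (`match_events()`, `error_report()`,
  `count_extra_events()`): ME, MAE, IQR, SD over successes, MAX, SR
  (within 16 ms), DR (within 1000 ms), extra-event counts;
* fusion-weight tuning by event RMSE (`tune_weights()`);
* a synthetic slow-walking simulator (`simulate_trial()`) with clean,
  foot-drag and cross-plate strike conditions and known ground truth, so
  the entire pipeline is testable without any data download;
* a command-line pipeline (`inst/cli/gaitevents.R`) with `simulate`,
  `detect-threshold`, `train`, `detect`, `evaluate` and `tune-weights`
  subcommands driven by YAML/JSON configs.

## Worked example

Simulate a minute of slow walking with a 20% foot-drag rate and run the
threshold baseline against the known schedule:

```r
library(gaitevents)

sim <- simulate_trial(sim_params(duration_s = 60, rate_hz = 100,
                                 drag_rate = 0.2, seed = 8))
sim$trial
#> <gait_trial> 'sim-8' (no_exo), body weight 700.0 N
#>   grf_left     6000 samples @ 100 Hz
#>   ...

baseline <- detect_threshold_events(sim$trial$channels$grf_left,
                                    sim$trial$body_weight_N, side = "L")
error_report(match_events(baseline, sim$truth, side = "L", type = "HS"))
#> <gait_error_report> n = 28
#>   ME 0.000 ms | MAE 0.000 ms | IQR 0.000 ms | SD 0.000 ms | MAX 0.000 ms
#>   SR 100.000 % | DR 100.000 %
count_extra_events(baseline, sim$truth, "L", "HS")
#> [1] 3
```

Every true event is found at the exact sample (the threshold convention
defines the simulator's ground truth), but each drag blip that crosses 1%
of body weight adds a spurious contact — here three extra heel strikes in
one minute.  The fused LSTM detector is trained and evaluated end-to-end
by the reference benchmark (two desk-preset models trained on 2 trials,
tested on 38; about five minutes on one CPU core):

```r
bench <- run_desk_benchmark(seed = 1)
bench$report
#> <gait_error_report> n = 13376
#>   ME 1.067 ms | MAE 0.000 ms | IQR 0.000 ms | SD 2.910 ms | MAX 60.000 ms
#>   SR 98.684 % | DR 100.000 %
```

Despite the same 5% drag and cross-plate contamination, the fused detector
finds every event within the 1000 ms window (DR 100%), places 98.7% of
them within 16 ms of ground truth, and its mean signed error is about
1 ms — a single sample at this rate is 10 ms.

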