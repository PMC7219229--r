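# radarbeat

Contactless detection of *individual heartbeats* from the raw baseband of a
24 GHz continuous-wave (CW) Doppler radar, using a shallow artificial neural
network — together with a physics-based synthetic cohort generator so that
the entire chain can be trained, tested and benchmarked without any recorded
data.

## Who this is for

Researchers in radar-based vital-sign sensing and biomedical signal
processing who want a complete, reproducible reference implementation of the
ANN-on-raw-I/Q approach to beat-by-beat cardiac monitoring: no I/Q imbalance
calibration, no offset compensation, no phase demodulation on the detection
path, and sub-second latency.

## The method

Chest motion phase-modulates the reflected carrier; a quadrature receiver
yields two baseband channels

    I(t) = A_I cos(θ₀ + 4π x(t)/λ + Δθ(t)) + DC_I
    Q(t) = A_Q sin(θ₀ + 4π x(t)/λ + Δθ(t) + Δφ) + DC_Q

where `x(t)` is chest displacement (millimetres of breathing, sub-millimetre
ballistocardiographic ripples per heartbeat) and `λ ≈ 12.5 mm` at 24 GHz.
The detector:

1. decimates I and Q from 1 kHz to 100 Hz (zero-phase anti-alias filtering);
2. forms, for every sample, a 200-sample input — the last 1 s of I
   concatenated with the last 1 s of Q;
3. scores each window with a shallow feed-forward network (default
   `FF 20 1`: 20 tanh units, one sigmoid output; 4000 first-layer
   multiply–accumulates), trained by Levenberg–Marquardt on the MSE between
   the network output and a **binarized target**: a 400 ms pulse starting
   200 ms after each ECG R peak (Pan-Tompkins), bracketing the
   electro-mechanical R–J delay;
4. smooths the probability stream with a width-10 causal moving average,
   picks prominent peaks at least 0.5 s apart (the 120 beats/min resting
   bound), and inserts one midpoint beat wherever an interval reaches twice
   the running median of recent inter-pulse intervals (IPIs).

Evaluation is subject-wise k-fold cross-validation (beats counted and IPI
statistics compared against the ECG reference, Lilliefors-gated Wilcoxon
tests), so all reported performance is on subjects the network never saw.

## Worked example

```r
library(radarbeat)

# simulate a small cohort: 3 subjects, 60 s each
cohort <- generate_cohort(3, 60, seed = 42)
cohort[[1]]
#> <subject_recording> S01
#>   ecg: 15000 @ 250 Hz | i: 60000 @ 1000 Hz | q: 60000 @ 1000 Hz
#>   truth beats: 80

# train the default shallow network on two subjects
prep <- lapply(cohort[1:2], radarbeat:::prepare_subject)
ws <- radarbeat:::combine_windows(lapply(prep, `[[`, "windows"),
                                 ids = c("S01", "S02"))
ws <- radarbeat:::subset_windows(ws, sort(withr::with_seed(1,
        sample(nrow(ws$inputs), 3000))))
fit <- suppressWarnings(train_lm("FF 20 1", ws,
        train_config(max_epochs = 30, seed = 7)))
tail(fit$log, 2)
#>    epoch  mu train_loss  val_loss accepted
#> 29    29  10  0.1724871 0.1759267     TRUE
#> 30    30 100  0.1706756 0.1744206     TRUE

# detect heartbeats on the held-out third subject
det <- detect_heartbeats(fit$model, cohort[[3]], amplitude = 0.1)
det
#> <beat_detections> 71 beats (0 interpolated), amplitude 0.1

ref <- pan_tompkins(cohort[[3]]$ecg)
count_error(det$beats, ref)
#> [1] -15.47619
ipi_mre(det$beats, ref)
#> [1] 19.54196
```

Reading the numbers: the training loss (MSE against the 0/1 target) falls to
0.17 — the constant predictor would sit near 0.25 — and the detector finds
71 of the held-out subject's 84 beats (count error −15%). Two training
subjects are *not enough to generalize well*: each subject presents a
different radar operating-point phase, and coverage of that phase circle is
what drives unseen-subject performance. The cross-validated benchmark below,
which trains on eight subjects per fold, reaches a pooled count error of
about −1.5% with an IPI mean relative error of about 17%. `crossvalidate()`
(or `run_pipeline()` with a YAML config, or the `inst/cli/radarbeat.R`
command-line front end) runs that full protocol.

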