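# seatsway

Seated posturography from balance-board forces: CoP trajectories,
spectral band power, staged quality control, group statistics and a
classifier benchmark separating low-back-pain from healthy sway.

## The problem

Postural control is usually measured standing on a force plate, but
standing CoP mixes trunk control with lower-limb performance. Measuring
sway *seated* on a four-load-cell balance board isolates the
trunk-stabilizing musculature, which is where chronic low back pain
(LBP) expresses itself. The analytic question is whether seated sway —
summarized as the CoP path length and the power of its spectrum in
selected frequency bands — separates LBP subjects from healthy ones, and
whether standard classifiers can do the assignment automatically.

This package implements that analysis end to end for users who have (or
want to simulate) raw corner-force recordings: biomechanics and
rehabilitation researchers working with Wii-type balance boards.

## The model

From corner forces TL, TR, BL, BR (N) with total S and board half-width
w / half-length l (cm):

    x = w * ((TR + BR) - (TL + BL)) / S     (mediolateral)
    y = l * ((TL + TR) - (BL + BR)) / S     (anteroposterior)

Channels are zero-phase Butterworth low-pass filtered (order 3; cohort
cutoff by residual analysis or fixed) before the CoP is formed. Per
trial the pipeline extracts: track length `sum sqrt(dx^2 + dy^2)` (cm);
one-sided periodogram PSDs of the detrended ML/AP series, integrated
over eight windows between 0.001 and 10 Hz (band areas in cm^2, exact
under Parseval); mean per-cycle maximum acceleration (cm/s^2, cycles
delimited by AP-velocity zero crossings); and ellipticity
`sqrt(lambda1/lambda2)` of the sway cloud. Staged QC removes protocol
failures, implausible values (> 1e6) and values outside the 0.9-IQR
fence. Group statistics are Welch t-tests per feature (difference on
the no-pain-minus-pain convention) and factorial ANOVA (Type II SS) with
eta^2, omega^2 and noncentral-F post-hoc power. Four classifiers (RBF
SVM, CART, random forest, single-hidden-layer network) are benchmarked
on 10 repeated 70/30 splits, identical per run across models, with
train-fitted min-max normalization.

A seeded synthetic-cohort generator (narrowband stochastic oscillators
per pendular anatomy + drift + noise, inverted exactly to corner forces)
stands in for clinical recordings; its group defaults are calibrated to
the published contrast directions (healthy: longer, circular tracks;
LBP: ~4x low-frequency band power, elliptical, higher per-cycle
acceleration). See the methods vignette
(`vignettes/seated-posturography.Rmd`) for every convention and design
choice.

## Worked example

```r
library(seatsway)
cfg <- sway_config(filter_cutoff_hz = 10, rng_seed = 1)
run <- run_pipeline(cfg, n_per_group = 50)   # simulate 50 + 50 subjects
print(run)
```

```
Seated-posturography pipeline run
  100 subjects, 77 retained after QC; cutoff 10.00 Hz

Group comparisons (no-pain vs pain):
         feature mean_no_pain mean_pain difference   p_value
 track_length_cm    87.602548 7.480e+01 12.8007234 1.287e-02
   band_0p001_10     0.029486 1.077e-01 -0.0781667 5.714e-10
    band_0p001_4     0.028347 1.070e-01 -0.0786297 4.394e-10
        band_1_4     0.007327 3.752e-03  0.0035750 8.959e-06
  mean_max_accel    69.563379 7.767e+01 -8.1049388 2.980e-02
     ellipticity     1.252455 2.325e+00 -1.0721103 3.440e-30
  [...]

Classifier benchmark: 10 repeats, 0.7/0.3 split, seed 1
  Type           Result [%] SD
  svm            96.09      +/-3.81
  tree           84.35      +/-6.22
  random_forest  96.52      +/-5.72
  nn             100.00     +/-0.00
```

Reading it: staged QC retained 77 of 100 trials. The healthy group walks
the longer CoP path (87.6 vs 74.8 cm, difference +12.8 cm) while the
pain group turns over several times more spectral power below 10 Hz
(0.108 vs 0.029 cm^2, difference negative on the no-pain-minus-pain
convention, p ~ 6e-10) and sways in a markedly more elliptical pattern
(2.33 vs 1.25). On these synthetic cohorts the groups are separable by
construction, so all four classifiers clear 60% mean accuracy with the
network near-perfect; clinical data are noisier.

A command-line front-end with `simulate`, `features`, `stats`,
`benchmark` and `run-all` subcommands lives at `inst/cli/seatsway.R`.

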