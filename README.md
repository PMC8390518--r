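# cel7track

Single-particle-tracking analysis of the cellobiohydrolase **Cel7A** on
immobilized cellulose, built around a three-state kinetic model.

Cel7A degrades crystalline cellulose by processively cleaving cellobiose
units from the reducing end of a glucan chain. In single-molecule TIRF
experiments, most Qdot-labelled enzymes bind to cellulose and sit still for
tens of seconds before dissociating; a minority move processively at a few
nm/s for a few tens of nm; and a few percent make abrupt >10 nm "jumps" —
unbinding, diffusing briefly in solution, and rebinding nearby. The package
is for single-molecule biophysicists who want to analyze such trajectories
(their own, or synthetic ones) with the complete chain used in that kind of
study:

* **`sim_config()` / `simulate_experiment()`** — a stochastic generator for
  the three-state scheme (solution ⇌ static ⇌ processive), producing
  per-frame trajectories with localization noise, stage drift and jumps;
  optionally rendered into 16-bit TIFF stacks with fiducial beads
  (`render_movie()`, `write_stack()`).
* **`localize_stack()` / `link_spots()` / `correct_drift()`** — sub-pixel
  2D Gaussian spot localization, greedy nearest-neighbour tracking, and
  fiducial-based drift correction.
* **`segment_trajectory()` / `apply_filters()`** — classification into
  static segments (within 10 nm of an anchor), processive segments
  (≥10 nm sustained for ≥5 s) and jumps (>10 nm within two frames,
  re-association within 100 nm), plus the study's inclusion filters
  (≥10 s bound, landed within 500 s, ≤510 s).
* **`fit_exponential_mle()` / `branching_fractions()` / `derive_rates()`**
  — windowed-exponential dwell-time MLE with bootstrap CIs, exit-route
  counting with detection-limit corrections, and derivation of the four
  rate constants and landing split of the three-state model:

  k_exit,processive = 1/τ_p = k_off,processive + k_static
  k_exit,static = 1/τ_s = k_off,static + k_processive

* **`run_pipeline()`** — orchestration of the stages with one master seed
  and a run manifest.

The numbered scripts under `analysis/` walk through a complete synthetic
study (simulate → localize demo → segment → fit), writing tables under
`results/`. The methods vignette
(`vignettes/three-state-kinetics.Rmd`) documents the model, the
segmentation algorithm, the estimators and their detection-limit
corrections.

## Worked example

```r
library(cel7track)

cfg <- sim_config(n_molecules = 2000, rng_seed = 11)   # study conditions
sim <- simulate_experiment(cfg)
p   <- segmentation_params()
seg <- segment_cohort(sim$trajectories, p, movie_end_frame = cfg$n_frames - 1)
fl  <- apply_filters(seg, p)
fl$report
#>   n_input n_short n_long n_late n_retained
#> 1    1989     162      9      0       1818

fits <- fit_all_dwells(dwell_samples(fl$retained), p,
                       boot_iterations = 1000, seed = 2)
fits$static_molecule
#> <exp_fit> static_molecule: tau = 90.3 s (95% CI 85.4-94.8), n = 1680
fits$processive
#> <exp_fit> processive: tau = 19.6 s (95% CI 16.4-23.1), n = 139

rates <- derive_rates(fits, branching_fractions(fl$retained, p))
rates
#> <three_state_rates> (s^-1)
#>   processive exit 0.05104 = k_off_processive 0.01455 + k_static 0.03649
#>   static exit     0.01114 = k_off_static     0.01055 + k_processive 0.0005836
#>   landing split: static 0.948 / processive 0.052
```

Reading the output: the cohort's static binding events have an
exponential time constant near 89 s and the processive segments near
20 s, so the total exit rates are ≈0.011 s⁻¹ and ≈0.049 s⁻¹; splitting
them by the observed exit routes (with the detection-limit corrections
described in the vignette) recovers the generator's four rate constants,
and the landing split comes back at ≈94% static. `build_report()` turns
the same objects into the full measured-parameter table.

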