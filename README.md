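# ramresp

Respirometry and accelerometry analysis for large, free-swimming fishes
that must swim to ventilate (obligate ram ventilators such as carcharhinid
sharks and tunas).

Such animals have no measurable resting metabolic rate and cannot hold
station in a swim tunnel, so metabolic phenotyping uses a large annular
intermittent-flow respirometer with a dorsal-fin accelerometer quantifying
the activity that cannot be controlled. `ramresp` turns the raw logger
outputs of that design into physiological endpoints:

- **MO2 records** from sealed-period oxygen declines:
  `MO2 = −b × 3600 × (V − V_animal) / W` (mg O2 kg⁻¹ h⁻¹), with an R² ≥ 0.8
  quality filter and a linear blank-run correction for microbial
  respiration.
- **MMR, mRMR and aerobic scope** as the means of the top/bottom 10% of
  normoxic records (mRMR — minimum routine metabolic rate — stands in for
  standard metabolic rate in fish that must keep swimming).
- **Critical oxygen limits**: the first metabolic-rate record below mRMR
  with all later records also below it starts a suffix whose regression on
  oxygen concentration is intersected with mRMR to give C_crit (mg l⁻¹),
  then S_crit (% saturation, via Benson–Krause solubility) and P_crit
  (mmHg, via ambient pO2).
- **Activity metrics** from 25-Hz triaxial acceleration: 3-s static/dynamic
  split, ODBA, and tailbeat frequency/amplitude (TBF/TBAA) from an analytic
  Morlet continuous wavelet ridge, amplitude-calibrated so a sinusoid of
  amplitude A returns TBAA = A.
- **Activity–metabolism inference**: animal-level mixed models with
  within-animal AR(1), BIC model selection, percentile cluster-bootstrap
  intervals, the pre/post-C_crit "crash" indicator, and paired temperature
  contrasts of MMR/mRMR/AS/P_crit.
- **A trial simulator** with known ground truth (chase-elevated recovery,
  oxyregulation above and linear oxyconformity below C_crit, drifting
  microbial background, sensor noise, coupled tailbeat signal) so the whole
  pipeline is testable end to end.

## Worked example

Simulate a trial under the default protocol (1500-l respirometer, 5-kg
animal, 20 h normoxia then stepwise hypoxia) and analyse it:

```r
library(ramresp)

cfg   <- sim_config(seed = 1, accelerometer = FALSE)
trial <- simulate_shark_trial(cfg)

recs <- fit_mo2_records(trial$oxygen_trace, trial$schedule,
                        trial$spec, trial$conditions)
bg   <- estimate_background(rbind(
  fit_blank_rate(trial$blanks$pre,  1500, trial$blanks$mid_times_h["pre"]),
  fit_blank_rate(trial$blanks$post, 1500, trial$blanks$mid_times_h["post"])))
recs <- apply_background_correction(recs, bg, trial$spec)

qc   <- recs[recs$qc_pass, ]
summ <- metabolic_summary(qc[qc$phase == "normoxic", ])
summ
#>        mmr     mrmr aerobic_scope n_records_used k_top k_bottom
#> 1 302.9875 153.4298      149.5577             27     3        3

detect_crit(qc[qc$phase == "hypoxic", ], summ$mrmr, trial$conditions)
#> critical oxygen level: C_crit 3.47 mg/l | S_crit 53.9% | P_crit 82.6 mmHg (n = 4)
```

The generating truth here was mRMR 150, MMR 330 (chase boost 2.2) and
C_crit 3.4 mg l⁻¹: the routine floor is recovered within ~2%, the critical
concentration within ~0.1 mg l⁻¹, and the top-10%-of-windows MMR estimator
sits, as designed, below the instantaneous chase peak (window averaging
over a recovering rate). `run_pipeline()` performs the same analysis from
CSV files (oxygen log, accelerometer log, blanks, schedule) given a YAML
run config, writes per-stage CSV/JSON outputs plus a seeded, hashed run
log, and `simulate_to_files()` writes a complete simulated bundle it can
consume. A thin command-line wrapper with `simulate` / `analyze` /
`fixtures` subcommands is installed at `inst/cli/ramresp.R`.

The packaged cohort table (13 juvenile sandbar sharks, 2.56–7.76 kg,
79.5–113.5 cm total length) is available via `load_animal_fixture()` and
`fixture_stats()`.

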