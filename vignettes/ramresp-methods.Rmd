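---
title: "Methods: respirometry and biologging analysis for free-swimming ram ventilators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry and biologging analysis for free-swimming ram ventilators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramresp)
```

## The measurement problem

Obligate ram ventilators (tunas, many carcharhinid sharks) must swim
continuously to irrigate their gills, so they have no measurable standard
metabolic rate in the usual sense and cannot be confined to a swim-tunnel
respirometer at a controlled speed. The workable design is a large annular
intermittent-flow respirometer in which the animal swims freely, with a
dorsal-fin accelerometer quantifying the activity that can no longer be
controlled. `ramresp` implements the full analysis for that design:

1. **Respirometry.** The system alternates a sealed measurement period with
   a flushing period. Each measurement period is an equilibration interval
   (default 3 min) followed by a recording span (default 12 min) over which
   oxygen declines linearly; the mass-specific metabolic rate is

   $$\dot{M}\mathrm{O}_2 = -b \times 3600 \times \frac{V - V_{animal}}{W}$$

   with $b$ the OLS slope of oxygen concentration on time (mg l⁻¹ s⁻¹),
   $V$ the tank volume (l) corrected for the animal's volume, and $W$ the
   body mass (kg). Records with regression $R^2 < 0.8$ are retained but
   flagged and excluded from inference (poorly mixed water or probe
   contact); a zero-variance window has $R^2$ defined as 0 so flat traces
   are filtered rather than treated as perfect fits.
2. **Background correction.** Microbial respiration is measured in blank
   runs (no animal, ≥ 3 h) before and after the trial; a straight line
   through the blank whole-tank rates is evaluated at each record's
   mid-time and subtracted at the tank level before mass normalisation.
3. **Metabolic metrics.** MMR and mRMR are the means of the top and bottom
   10% of QC-passing normoxic records ($k = \max(1,
   \mathrm{round}(0.1n))$, half-up), a deliberately outlier-resistant pair
   of estimators; aerobic scope is their difference. The 10% rule means the
   recovered "MMR" is a window-averaged quantity and sits below the
   instantaneous post-chase peak whenever recovery is fast relative to the
   measurement cycle — an accepted property of the estimator, not a bug.
4. **Critical oxygen.** During stepwise hypoxia, the suffix rule finds the
   first record whose metabolic rate falls below mRMR with all later
   records also below it; a linear regression of those rates on oxygen
   concentration is intersected with mRMR to give $C_{crit}$ (mg l⁻¹),
   converted to $S_{crit}$ (fraction of air saturation) through the
   solubility function and to $P_{crit}$ (mmHg) through the ambient oxygen
   partial pressure. A two-segment least-squares variant is available
   (`method = "two_segment"`) but the suffix rule is the default. Suffixes
   shorter than 2 records or with non-positive slope return "not found"
   rather than extrapolating.
5. **Activity metrics.** Raw 25-Hz triaxial acceleration is split into a
   static (gravity) component — a centred 3-s moving average, matched to a
   ~1-Hz tailbeat — and a dynamic remainder; the decomposition is exact by
   construction. ODBA is the sum of absolute dynamic components (the
   field-standard rectified definition: the raw sum would average to ~0).
   TBF and TBAA come from an analytic Morlet continuous wavelet transform
   (ω₀ = 6) of the dynamic sway (z) axis on a log-spaced grid over
   0.2–3 Hz: per sample, the ridge is the in-band amplitude maximum refined
   by quadratic interpolation, TBF its frequency and TBAA its
   amplitude-calibrated magnitude (a pure sinusoid of amplitude A returns
   TBAA = A, verified on an amplitude-by-frequency sinusoid grid in the
   test suite). Samples whose ridge
   amplitude falls below 0.02 g have TBF undefined; swim stops are maximal
   intervals with TBAA < 0.05 g lasting ≥ 5 s.
6. **Inference.** Per-period activity and metabolic records are joined on
   the measurement-period index; the normoxic/hypoxic phase boundary is 80%
   saturation (closed on the normoxic side), and the binary crash metric
   marks hypoxic records preceding the first record at or below
   $C_{crit}$. Mixed models (`nlme::lme`, maximum likelihood) with animal
   random intercepts, optional within-animal AR(1) over period order and
   optional per-temperature residual variances are compared by BIC (ties
   within 2 units resolved toward fewer parameters). Uncertainty comes from
   a percentile cluster bootstrap that resamples whole animals; paired
   temperature contrasts of MMR, mRMR, AS and $P_{crit}$ use per-metric
   mixed models with estimated marginal means ("second minus first" sign
   convention).

## Unit and conversion choices

- **Slope units.** $b$ is in mg O₂ l⁻¹ s⁻¹; the ×3600 factor yields
  mg O₂ kg⁻¹ h⁻¹, the only reading of the rate equation dimensionally
  consistent with its stated output units.
- **Animal volume.** 1 l per kg body mass (neutral buoyancy), since only
  "volume-corrected" is specified by the design.
- **Solubility.** Benson–Krause fit with salinity and pressure factors.
  Default salinity is 35 psu: the coastal-lagoon systems this design is
  used in run near-oceanic salinity, and the package's reconstruction of a
  51%-saturation critical level at 28 °C (0.51 × 6.44 = 3.29 ≈ 3.3 mg l⁻¹)
  is only consistent at that salinity. Default barometric pressure
  760 mmHg. Vapour pressure uses a standard freshwater formula
  (28.35 mmHg at 28 °C; the correction is < 4% over 24–32 °C).
- **Time base.** Seconds since the end of the chase (= trial start);
  windows are half-open `[start, end)`.

## The trial simulator and what it emulates

No public data accompany this experimental design, so the package ships a
simulator (`sim_config()`, `simulate_shark_trial()`) whose defaults encode
the study protocol: a 1500-l respirometer, 30-min flush / 15-min measure
cycles starting with a sealed measurement immediately after a 10-min chase,
~20 h of normoxia, then stepwise hypoxia (80 → 30% saturation in 10-point
steps held 1.5 h) giving at least three measurement periods below the
critical level. The generating physiology:

- **Post-chase recovery** is a single exponential from `chase_boost` × mRMR
  (default 2.2 × 150 mg O₂ kg⁻¹ h⁻¹) toward mRMR with a 5-h time constant —
  chosen so recovery is ~98% complete at the 20-h mark, matching a protocol
  sized to let the animal "level out" overnight. The chase multiple and the
  kinetics are free parameters because neither is quantified for this
  design; both defaults are documented choices.
- **Oxyregulation and collapse.** Above $C_{crit}$ (default 3.4 mg l⁻¹)
  during hypoxia the metabolic rate is elevated by `hypoxic_effort`
  (default 1.1): ram ventilators swim harder and widen gape as oxygen
  falls, and regulating rates in this design sit clearly above the mRMR
  floor — without that elevation the suffix rule is unidentifiable, since
  noise drops plateau records below the estimated floor. Below $C_{crit}$
  the rate declines linearly in oxygen (slope 40 mg O₂ kg⁻¹ h⁻¹ per
  mg l⁻¹), so the conforming limb intersects mRMR exactly at the generating
  $C_{crit}$ and the estimator's target is well defined.
- **Tank dynamics.** One well-mixed compartment: sealed windows decline at
  (animal consumption + background)/effective volume; flushing relaxes
  exponentially toward the reservoir (300-s mixing constant). Microbial
  background drifts linearly (5 → 10 mg O₂ h⁻¹ whole-tank) and blanks are
  generated 3 h before and after the trial. Sensor noise is Gaussian,
  0.01 mg l⁻¹ at 1 Hz (an optical optode); at the default geometry this
  yields window $R^2 \approx 0.9$ in normoxia, with occasional QC failures
  in the deepest hypoxia step where the decline is shallowest — the
  realistic regime for the 0.8 filter.
- **Activity.** The sway axis carries a tailbeat sinusoid (base 1.0 Hz,
  0.3 g) whose frequency follows relative metabolic rate above $C_{crit}$
  and decouples below it, emulating the observed breakdown of the
  activity–metabolism correlation; smaller in-phase x/y components (20% and
  10%) and a constant gravity projection complete the signal. Stop bouts
  zero the dynamic component. The simulator does **not** attempt
  hydrodynamic or biomechanical realism (no banking geometry, no posture
  changes, no amplitude–frequency trade-offs), so passing recovery tests
  demonstrates correctness of the estimators under the stated model, not
  robustness to every behaviour of a real shark.

Identical configurations (including seed) give bit-identical traces.

## Numerical choices and degenerate inputs

- OLS slopes and $R^2$ are computed from centred sums; a zero-variance
  response has $R^2 := 0$.
- The Morlet ridge uses the energy-peak scale-to-frequency convention
  $f = \omega_0 / 2\pi s$, under which the calibrated amplitude of a
  sinusoid peaks exactly at its own frequency; the Fourier-period
  convention would bias ridge frequencies by +1.4% at ω₀ = 6.
- `fit_model` guards the mixed fit three ways: an essentially exact linear
  fit and zero within-animal residual variance both short-circuit to OLS
  (the correct degenerate limits, where the mixed likelihood is unbounded);
  and because the ML mixed model nests OLS, a fitted log-likelihood below
  the OLS value proves optimiser failure and triggers a retry, then an OLS
  fallback. Non-convergence yields `converged = FALSE` with infinite BIC.
- Cluster bootstrap resamples animals with replacement and relabels the
  copies, so rows are never mixed across animals within a resample.

## Problem sizes used in validation

The shipped tests recover the generating physiology over 20 seeds of the
full default protocol (oxygen channel), verify wavelet calibration on a
9-point sinusoid grid, check the suffix rule against exhaustive search on
1000 random record sets, and validate BIC subset recovery over 50 seeds at
effect sizes ≥ 5 residual standard deviations. Bootstrap coverage is
verified over 200 replicates of an 80-animal cohort with 120 bootstrap
resamples each: the percentile cluster bootstrap's coverage deficit shrinks
roughly in proportion to 1/clusters, so many clusters are needed for it to
be approximately valid. With cohorts the size a single field
season yields (8–12 animals) the same intervals **undercover
noticeably** — a known small-sample property of percentile cluster
bootstraps, worth remembering when reading uncertainty bands from small
cohorts. Multi-seed loops use a shortened normoxia phase where the
full 20-h trace is not needed by the quantity under test.

## Known limitations

- The repeated-measures machinery here (per-metric mixed models with animal
  random intercepts, AR(1) over period order) is a deliberate
  simplification of multivariate repeated-measures formulations with
  specialised degrees-of-freedom corrections; paired temperature contrasts
  are preserved, exact t-statistics from such software are not
  reproducible.
- Serial correlation treats QC-dropped periods as consecutive.
- The suffix rule requires the hypoxia protocol to actually cross the
  critical level with ≥ 2 records below the mRMR floor; shallow protocols
  return "not found" by design.
- TBAA calibration is defined against sinusoid amplitude; real tailbeats
  are only approximately sinusoidal.
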