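---
title: "Models and methods behind the BELA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the BELA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bela)
```

## The measurement and its statistic

Body electrical loss analysis measures the ohmic losses a body dissipates
when placed inside a resonant coil. The losses lower the coil's quality
factor, observed as an in-phase voltage change $\Delta V_i$ between the
empty and the loaded coil. The statistic of interest is the loss changing
rate between two excitation frequencies,

$$m_{loss} = \frac{\Delta V_{i,H} - \Delta V_{i,L}}{f_H - f_L},$$

in mV/kHz, with the defaults $f_L = 103$ kHz and $f_H = 185$ kHz. Both
frequencies are low enough that the field penetrates the whole trunk, and
far enough apart that the frequency dependence of tissue conductivity
(β-dispersion) shows up in the numerator. Repeatability propagates the
replicate standard deviations of the two voltage changes,

$$\Delta m_{loss} = \frac{\sigma_H + \sigma_L}{f_H - f_L},$$

a half-range estimate. Frequency-measurement uncertainty is orders of
magnitude below the voltage noise and is deliberately omitted. Voltage
changes are stored as positive loss magnitudes; a negative $m_{loss}$ is
physically suspect (losses should grow with frequency) and is flagged with a
warning but never clamped, so degenerate instrument states stay visible.
Replicates are aggregated marginally per frequency with the $n-1$ sample
standard deviation; no pairing of low/high sweeps is assumed, which is the
conservative reading when the acquisition order is unknown and is exactly
what the repeatability formula's per-frequency σ's require.

## Calibration statistics

Calibration regresses MRI visceral-fat area (cm²) on $m_{loss}$ by ordinary
least squares. The direction is fixed by units: the reported error measures
(SEE, leave-one-out RMSE) are in cm², which is only meaningful with area as
the response. SEE is $\sqrt{RSS/(n-2)}$; the leave-one-out RMSE refits the
line with each point held out — the hat-matrix shortcut is used only as an
independent oracle in the tests, never as the implementation, so the
refit-per-fold semantics stay honest for any future robustification.
Significance of a squared correlation uses the exact $t$ transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ degrees of freedom, two-sided.
The correlation table spans three abdominal levels (navel −5 cm, navel,
navel +5 cm — never pooled) and six covariates (VF, SF, VF/SF, SF/VF, BMI,
WC). No multiple-testing adjustment is applied across its 18 cells,
matching the original analysis; every report carries a note saying so.
Outlier handling is manual-first: `flag_outliers()` marks points with
|externally studentized residual| > 2.5 (a common default; the flag set at
2.5 is a superset of the one at 3.0), but exclusion always goes through the
explicit `exclude` argument, mirroring how a real exceptional subject is
excluded by anatomical inspection rather than by rule.

## The forward model

The abdomen is modelled as concentric conductive shells under a quasi-static
uniform axial field: an interior disc mixing lean tissue and visceral fat,
a muscle annulus of given thickness, and a subcutaneous-fat annulus. Radii
follow from areas, $r_{int} = \sqrt{(A_{lean}+A_{VF})/\pi}$,
$r_{musc} = r_{int} + t_m$, $r_{out} = \sqrt{r_{musc}^2 + A_{SF}/\pi}$, and
the implied waist circumference is $2\pi r_{out}$. The induced azimuthal
field grows as $f \cdot r$, so the dissipation integrates to

$$L(f) \propto \sum_{shells} \sigma_{shell}(f)\, f^2\, (r_{out}^4 - r_{in}^4),$$

per unit slice thickness. The $r^4$ weighting concentrates signal in the
outer conductive anatomy — together with the stronger lean-tissue
dispersion this reproduces, without invoking skin effect, the observation
that higher frequencies emphasize the outer shell. Skin effect is genuinely
negligible here: with the default muscle conductivity at 185 kHz the skin
depth exceeds a metre, more than ten times any body radius, which the test
suite asserts.

Choices made where the design was open:

- **Conductivity dispersion** is linear in $f$ over a 50–500 kHz validity
  window: σ₀(muscle) = 0.40 S/m, σ₀(fat) = 0.035 S/m at 100 kHz, slopes
  β = 0.25 and 0.05. The only hard constraint honoured is the ≥10× lean/fat
  contrast; the exact values are configuration, and the ≥10× guard can be
  relaxed explicitly for sensitivity analyses.
- **Interior mixing** is area-weighted and linear — a mixture of two linear
  dispersions is again linear, so it folds exactly into one parameter pair.
  Maxwell–Garnett mixing was rejected: at these contrasts it changes the
  mixture curve slightly but costs testability.
- **Loss→voltage mapping** is a single lumped gain (mV per loss unit),
  absorbing the unpublished coil constants. `calibrate_gain()` fixes it so
  the reference anatomy (lean 250 cm², VF 90 cm², SF 150 cm², muscle 2.2 cm)
  yields exactly 0.6 mV/kHz noise-free — the session-mean magnitude reported
  for the instrument (0.57–0.61 mV/kHz).
- **Geometry** is circular-cylindrical; elliptical sections are out of
  scope.

The model's qualitative content, all asserted by tests: $m_{loss}$ rises
monotonically with VF (VF pushes the high-conductivity muscle annulus
outward into larger $r^4$ weight); the SF sensitivity is under 0.3 of the
VF sensitivity at the reference anatomy; and a thin muscle sheath collapses
the rate at fixed VF — the thin-outside-fat-inside (TOFI) failure mode, in
which a calibration fitted on normal anatomies underestimates the depot by
well over 25 %.

## The synthetic cohort and its noise budget

The generator emulates a cohort with the feasibility study's statistical
structure, not its ten specific volunteers. Per subject: visceral-fat area
lognormal with median 90 cm² (σ_log = 0.6, spanning roughly 30–300 cm²),
subcutaneous area lognormal with median 150 cm² (σ_log = 0.4) and sampled
*independently* of VF — so an SF–rate correlation can only arise through
geometry, making the decoupling check meaningful; lean interior normal
250 ± 30 cm²; muscle thickness truncated normal 2.2 ± 0.4 cm with a 0.2 cm
floor. Adjacent levels share a latent subject factor (inter-level
correlation 0.9) plus a small deterministic level gradient (±3 %), which
yields the few-percent level-to-level rate differences seen in practice.
Waist circumference is derived from the navel-level geometry and rejected
outside 70–112 cm, bracketing the study's 73–108 cm; BMI comes from a height
draw and a cylindrical mass proxy and is a covariate only — the physics
never reads it.

Replicate noise has three parts applied in order to the noise-free voltage:
a multiplicative positioning deviation (Gaussian, CV 2.5 % at $f_L$ and
1.5 % at $f_H$ — the measured off-centre standing effect, read as
per-replicate jitter, the conservative choice for repeatability simulation),
additive electronic noise (0.55/0.30 mV), and ADC quantization (10-bit,
1.1 V, ±2 LSB uniform offset). The decomposition was chosen so the three
together reproduce the instrument's observed total replicate SDs of about
1.71 mV (low) and 1.89 mV (high); quantization dominates (±2 LSB alone
contributes ≈1.5 mV), matching the instrument's own accounting of its
accuracy floor, and the propagated mean relative repeatability lands in the
5–15 % band around the observed ±9.6 %. Day-to-day session variability is
not separately modelled (the three-day data showed it within replicate
noise); axial slice blur is likewise omitted — the ~5 cm effective slice
thickness of the coil would mix adjacent-level compositions and is left as
an extension.

What passing tests on this cohort do *not* show: real abdomens are
elliptical, layered irregularly, and carry organ-conductivity variation the
three-compartment model ignores; the generator's VF–rate relation is by
construction monotone, so the synthetic R² values say the pipeline recovers
a relation that exists, not that the relation exists in people.

## Numerical choices and degenerate inputs

Sample SDs need ≥2 replicates; calibration needs ≥3 points (≥4 for
leave-one-out; the refit errors name the offending index when a fold is
degenerate). Constant predictors and zero-variance cells raise explicit
degenerate-variance errors; in the correlation table they surface per cell
as `NA` plus a note instead of aborting the table. Ratio covariates drop
zero-denominator subjects with a warning. Outlier flagging treats a
numerically exact fit (residual SD below 1e-8 of the response scale) as
flagless, and a point whose deleted fit is exact while its own residual is
material as unconditionally flagged — both guards exist because externally
studentized residuals are 0/0 in those corners. ADC quantization bounds its
error by construction at (lsb_error + 0.5)·LSB and refuses voltages outside
the converter range, which in the simulator signals a gain
misconfiguration rather than clipping silently.

Problem sizes in the shipped analyses — 50 subjects for the correlation
structure, 10 for the repeatability budget, 21 (20 normal + 1 TOFI) for the
failure-mode quantification, 100 × n = 200 for slope-recovery coverage —
were chosen as the smallest sizes at which the respective statistics are
stable across seeds.

## Known limitations

The forward model is a stand-in for an instrument, not a validated
electromagnetic solver: no capacitive coupling (the real instrument shields
it away), no field inhomogeneity, no elliptical geometry, no Cole–Cole
dispersion. The voltage scale is anchored to a single published magnitude
(0.6 mV/kHz) and the published noise figures; absolute voltages are
therefore plausible, not measured. The calibration stage reports
unadjusted per-cell p-values by design. And the strong waist-circumference
correlation the pipeline reproduces is a genuine confound of the method
itself, not an artifact of this implementation — distinguishing geometric
from compositional signal is exactly what larger clinical studies would
need to settle.
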