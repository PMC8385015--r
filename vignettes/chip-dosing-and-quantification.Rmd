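---
title: "PK-mimicking dosing schedules and spheroid quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PK-mimicking dosing schedules and spheroid quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipPKPD)
```

# Scope

`chipPKPD` supports perfused tumour-spheroid ("tumour-on-chip") experiments
in which a pump switches sequentially between up to eight medium reservoirs,
each holding one drug concentration for a set time, so that the spheroids see
a stepwise approximation of an in vivo plasma pharmacokinetic (PK) profile
rather than a constant bath. The package covers the desk work around such an
experiment: PK simulation and fitting, discretisation of a continuous
profile into the reservoir schedule, composition of multi-day mono- and
combination regimens (including schedules where the second drug starts 24 h
or 72 h after the first), two-step dilution planning from DMSO stocks, a
pharmacodynamic (PD) simulator standing in for the wet-lab response, and
quantification of spheroid images (Feret-diameter volumetry and
biomarker-positive cell counts). The worked default data are the free plasma
profiles of SN38 (the active metabolite of irinotecan, a topoisomerase-I
inhibitor) and the ATM-kinase inhibitor AZD0156 in mouse, shipped as the
packaged reference series.

# Pharmacokinetic core

Free plasma concentration is modelled with a one-compartment disposition and
first-order absorption. For a dose $D$ at time $t_0$,

$$C(t) = f_u \frac{F D}{V} \frac{k_a}{k_a - k_e}
  \left(e^{-k_e (t - t_0)} - e^{-k_a (t - t_0)}\right), \qquad t \ge t_0,$$

with superposition across repeated doses (linear PK). $k_a$ and $k_e$ are the
absorption and elimination rate constants (1/h), $V$ the apparent volume,
$F$ the bioavailable fraction and $f_u$ the free fraction. Population-level
hierarchical structure is deliberately out of scope: the 24-h reference
profiles are single monotone-decline mean curves, and the simplest structure
that reproduces them is a per-curve one-compartment fit. Both oral and
intraperitoneal dosing are treated as first-order input.

Fitting (`fitPKParams()`) minimises squared residuals on log concentration
via Levenberg-Marquardt. Choices worth knowing:

* only the amplitude $A = f_u F D / V$ is identifiable from a concentration
  curve, so the returned parameters adopt $F = f_u = 1$, $V = D / A$;
* flip-flop ambiguity is removed structurally by the parameterisation
  $k_e = e^{\ell_1}$, $k_a = k_e + e^{\ell_2}$, which enforces $k_a > k_e$;
* rates are floored at $10^{-4}$/h; zero-concentration samples are excluded
  from the log residuals rather than imputed; fewer than four positive
  observations is treated as under-determined and rejected;
* starting values come from curve stripping: $k_e$ from a log-linear
  regression on the last four points, $k_a = 5 k_e$, amplitude from the
  observed peak. A stalled optimiser returns `converged = FALSE` rather than
  an error.

# From profile to reservoir schedule

`intervalMean()` gives the time-weighted mean of the linearly interpolated
profile over an interval (exact trapezoid, endpoints inserted). Tabulated
post-dose series that start at the first sampling time (1 h for the
reference data) are first extended with a zero sample at $t = 0$ by
`prependZero()`; no extrapolation beyond the support is ever performed.

The default boundary rule (`equalAucBoundaries()`) partitions the profile
into intervals of equal area under the curve. The published reservoir table
does not state how its interval boundaries were chosen, so the package picks
the exposure-preserving rule: with interval-mean step concentrations on an
equal-AUC partition, the stepwise schedule reproduces the profile AUC
exactly (up to the 3-significant-figure rounding of step concentrations),
and the $L_1$ mismatch to the reference decreases as steps are added.
Within each knot interval the cumulative AUC is quadratic in time, so
boundaries are solved in closed form rather than on a grid.

`buildExposureSchedule()` assigns each interval its mean concentration,
rounded to 3 significant figures (the rounding that turns the observed
192.1 nM peak into the 192 nM reservoir value). Two policies govern the
peak step:

* `peakPolicy = "mean"` (default) — every step is an interval mean; AUC is
  conserved.
* `peakPolicy = "cmax"` — the step whose interval contains Tmax is anchored
  at the profile maximum. This matches the platform convention visible in
  the reference table, whose first reservoir holds each drug's Cmax (5.5 nM
  SN38, 192 nM AZD0156) rather than the first-hour average; the price is a
  slight AUC overshoot, which is why it is not the default.

The transcribed reference schedule (`referenceSchedule()`) has seven drug
steps of 1, 3, 2, 3, 3, 4 and 8 h (summing to the 24-h cycle) on reservoirs
2-8, with reservoir 1 holding drug-free medium; its boundaries are exposed
as `referenceBoundaries()` and can be passed to `buildExposureSchedule()`
directly. The extracted source table is ambiguous about these durations;
this parsing is the only one found under which they sum to 24 h.

Timelines (`composeTreatmentTimeline()`) place a drug's 24-h schedule at the
start of each dosing day, day 1 beginning at $t = 0$, intervals half-open
$[{\rm start}, {\rm end})$, ties in Tmax resolved to the earliest time. The
five standard regimen tokens are `mono`, `combo_1_7`, `combo_7_7`,
`combo_gap24` (partner on days 2-4) and `combo_gap72` (days 4-6) over a
7-day cycle. Exposure metrics (AUC, Cmax, Tmax, time above threshold,
mismatch $\int |{\rm schedule} - {\rm reference}|$) are computed exactly on
the piecewise-linear/piecewise-constant representations, including crossing
detection inside segments.

# Dilution planning

`planTwoStepDilution()` computes stock → intermediate → reservoir transfers
with mass conservation (volume × concentration) at every step. Two printed
conventions coexist in practice and both are supported: the intermediate can
be derived from the top reservoir concentration times a second-step factor
(default 100; 192 nM × 100 = 19.2 µM for the ATMi from a 1 mM stock), or
from a round first-step stock dilution (`firstStepFactor`; 0.1 mM SN38 / 100
= 1 µM). Note the two rules disagree for SN38 (5.5 nM × 100 would give
0.55 µM, not the printed 1 µM), which is why the planner exposes both.
Reservoir volumes come from `reservoirVolumeRequirement()`: flow rate ×
duration + 5 mL spare at the platform's 20 µL/min default. The DMSO cap
defaults to 0.1% v/v — a common cell-culture tolerance, chosen here because
the source protocol is silent — and the minimum pipettable volume to 0.5 µL;
plans violating either are rejected with the offending reservoir named.

# Pharmacodynamic simulator

The PD module is an explicitly synthetic stand-in for wet-lab readouts; the
underlying study reports outcomes, not a mechanistic model. The package's
model couples an Emax kill term for the TOP1 inhibitor to a latent damage
state $\,D$ that gates the ATM-inhibitor effect:

$$\frac{dV}{dt} = k_g V - V \left[ E_{S} \frac{C_S}{EC50_S + C_S}
  + \alpha D \, E_{A} \frac{C_A}{EC50_A + C_A} \right], \qquad
\frac{dD}{dt} = k_{in} C_S - k_{out} D .$$

$D$ accumulates while SN38 is present and resolves at rate $k_{out}$, so
ATMi delivered after SN38 still potentiates kill in proportion to the damage
remaining — the mechanism by which a 24-h gap retains most of the
combination benefit and a 72-h gap loses much of it. A purely multiplicative
potentiation gated on the *current* SN38 concentration was considered and
rejected: with SN38 cleared within a day, it makes every gapped schedule
identical to monotherapy and cannot express the observed gap sensitivity.
The additive damage-gated form keeps the required structural properties:
$\alpha = 0$ decouples the combination exactly, and the day-7 volume is
non-increasing in $\alpha$ under any fixed schedule.

Numerics: fixed-step RK4 on $(\log V, D)$ at $\Delta t = 0.01$ day, volume
floored at $10^{-12} V_0$; the piecewise-constant timeline is evaluated
inside RK4 stages, so discontinuities at step switches are handled by the
fixed grid. Noise-free output is bitwise reproducible; measurement noise is
a separate seeded log-normal observation step (`observeVolumes()`).

Calibration: $k_g = 0.273$/day makes the untreated control grow ~6.8-fold
over 7 days, the fold jointly implied by the published %GI and
relative-volume readouts (e.g. 55% relative volume with 52% GI for
monotherapy are mutually consistent only near this fold). The remaining
parameters ($E_S = 1.19$/day, $EC50_S = 0.7$ nM, $\alpha = 1.35$,
$k_{out} = 1.44$/day, with $E_A = 1$/day, $EC50_A = 50$ nM, $k_{in} = 1$
/(nM day) fixed) come from a coarse grid search (`scripts/calibrate_pd.R`)
that minimises squared log-distance to the five published day-7 relative
volumes subject to reproducing their ordering
(control > mono > gap72 > gap24 > 1-day combo > 7-day combo). The defaults
live in a versioned YAML file and are loaded by `defaultPDParams()`. The
simulator is used for ordering and schedule-comparison properties only; no
claim of mechanistic truth or quantitative in vivo reproduction is made.

Percent growth inhibition follows the volume-change definition
$\%GI = 100\,(1 - \Delta V_T / \Delta V_C)$ and is undefined (rejected) when
the control fails to grow; it is invariant to volume rescaling and can
exceed 100% under regression.

# Imaging

The synthetic generator (`generateSyntheticSpheroid()`) emulates what the
quantification pipeline needs to be tested against: a roughly circular
(optionally elliptical, rotatable) spheroid of the platform's typical
250-370 µm diameter rendered dark on a bright brightfield background, nuclei
of ~4 µm radius placed by seeded Poisson-disc (dart-throwing) sampling and
rendered as Gaussian spots, marker channels lighting a seeded random subset
of nuclei at a requested positive fraction, and additive Gaussian background
noise. Ground truth (mask, centroids, positive labels) is recorded. It does
*not* emulate out-of-focus light, Matrigel autofluorescence, intensity
gradients across a 3-D spheroid, touching/overlapping nuclei, or staining
heterogeneity — so passing benchmarks demonstrate correctness of the
geometry and counting logic, not robustness to every real-microscopy
artefact.

Quantification follows the study's measurement chain:

* segmentation: Gaussian smoothing (σ = 2 px), global Otsu threshold with
  the spheroid dark on a bright background, largest 8-connected component,
  hole filling; a uniform image is rejected as "no spheroid detected";
* Feret diameters: rotating projections of the convex hull of the mask at 1°
  resolution, +1 px per extent for pixel width, scaled by pixel size;
* volume: average radius $(F_{min} + F_{max}) / 4$ — the straightforward
  reading of "average radius deduced from min/max Feret" — and sphere volume
  $\tfrac{4}{3}\pi r^3$;
* nuclei: background-subtracted smoothing, local maxima at a minimum
  separation of twice the nucleus radius, restricted to the mask;
* positivity: mean marker intensity within one nucleus radius exceeding the
  background mean + 3 SD, the background being the region outside the
  dilated mask. The original analysis used ImageJ macros whose thresholds
  are not published; this rule is the package's documented substitute and
  the `k` multiplier is configurable. DNA-damage (γH2AX) and apoptosis (CC3)
  markers are reported per 10⁴ µm² of spheroid area; the proliferation
  marker Ki67, present in all cycling cells, is reported as a fraction of
  nuclei and needs no area normalisation.

Pixel conventions: 0-based coordinates, areas as pixel counts × pixel size²,
8-connectivity throughout.

# Reproducibility and problem sizes

A single run seed fans out to per-module seeds through a fixed counter
scheme (`moduleSeed()`), so each module is independently reproducible. The
test-suite and acceptance problem sizes — 24-point PK series, 8-step
schedules, 7-day simulations at $\Delta t = 0.01$ day, ~300-nucleus images
at 1 µm/px — are the package's working scale: large enough for every
tolerance quoted above to be meaningful, small enough that the whole suite
runs in well under a minute.

# Known limitations

Nonlinear (saturable) PK, prodrug-to-metabolite conversion, and hierarchical
population fitting are out of scope. The PD model is a calibrated synthetic
device, not a validated tumour-growth-inhibition model; its quantitative
outputs should only be read as orderings. The imaging pipeline is 2-D
projection-based (as is the measurement chain it implements) and does not
attempt 3-D reconstruction or focus-level morphology of damage foci.
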