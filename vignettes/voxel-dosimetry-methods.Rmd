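---
title: "Voxel Monte Carlo dosimetry for radionuclide therapy: models and methods"
author: "voxdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel Monte Carlo dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

# The problem

In radionuclide therapy with a ^177^Lu-labeled peptide, the red bone marrow
(RBM) is usually the dose-limiting organ, and the clinically interesting
question is whether a patient's marrow dose predicts hematologic toxicity.
`voxdose` implements the full computational chain of a serial-imaging
dosimetry study: quantitative SPECT calibration, a Monte Carlo voxel
dose-rate engine driven by activity, density and composition maps, hybrid
trapezoidal-exponential time integration, three competing RBM dose methods
(3D image-based on the lumbar vertebrae, blood-based, and 2D cranium-based),
the linear-quadratic biologically effective dose (BED) with the
Lea-Catcheside protraction factor, tumor dose-volume histograms with an
OLINDA-style sphere-model comparison, and matched-pair simulation of ^90^Y
therapy from ^177^Lu images. Because no patient imaging is distributed with
the cohort tables, a synthetic digital phantom generator with exact analytic
ground truth stands in for the patient data in every end-to-end test.

# The dosimetric model

## Monte Carlo voxel dose rates

Each acquisition provides an activity map $A_v$ (MBq per voxel). The engine
samples decay locations proportional to $A_v$, uniformly within the voxel,
and transports the nuclide's emissions through the density map $\rho_v$
(g/cm^3^) and a three-material composition map (soft tissue, lung, bone)
derived from density thresholds (lung below 0.5, bone above 1.2 g/cm^3^).

* **Beta particles.** For ^177^Lu the mean beta energy (0.1333 MeV) has a
  continuous-slowing-down range of about 0.2 mm in unit-density tissue —
  far below the 4.795 mm voxel — so beta energy is deposited in the source
  voxel. For ^90^Y (mean ~0.93 MeV, endpoint 2.28 MeV) the range reaches
  the centimetre scale, so each history samples an energy from the
  allowed-transition Fermi spectrum shape and walks a straight path through
  the density map, depositing the CSDA energy-loss profile voxel by voxel.
  Straight-path CSDA transport (rather than a precomputed radial kernel)
  was chosen because it respects density heterogeneity at no extra model
  cost; full condensed-history electron scattering is deliberately out of
  scope, as is bremsstrahlung.
* **Photons.** ^177^Lu's two imaging lines (112.95 keV at 6.20%, 208.37 keV
  at 10.36% per decay) are emitted isotropically with statistical weight
  equal to their yield and tracked by Woodcock (delta) tracking against a
  grid-wide majorant cross-section. At a real interaction, photoelectric
  absorption deposits the full energy locally; Compton scattering samples
  the Klein–Nishina ratio by Kahn's rejection method, deposits the electron
  energy on the spot (kerma approximation — electron ranges are sub-voxel at
  these energies), and follows the scattered photon until it falls below
  the 20 keV cutoff (deposited locally) or leaves the grid (booked as
  escaped). Coherent scattering is ignored. Mass attenuation coefficients
  for soft tissue/water and cortical bone are bundled on a 20 keV–1 MeV
  grid, interpolated log-log.
* **Energy ledger.** Every run reports emitted, deposited and escaped
  energy; these balance to double precision by construction, and the
  validity method of the result class enforces the balance at 1e-9
  relative. Voxel dose rate (Gy/h) is the tallied energy times the decay
  rate the run represents, divided by the voxel mass from the density map
  floored at 0.05 g/cm^3^ (so near-void voxels cannot acquire unbounded
  dose).

Decay data are versioned package data (`inst/extdata/nuclides.yaml`), not
constants in code. Half-lives follow the protocol values (6.71 d for
^177^Lu, 2.66 d for ^90^Y). The ^90^Y spectrum is generated from its
endpoint and daughter charge with the nonrelativistic Fermi Coulomb
correction; its mean is validated in the tests against the tabulated
reference mean (0.9337 MeV) at 2%.

## Time integration: the hybrid trapezoidal-exponential rule

Four samples $y_1 \dots y_4$ at times $t_1 \dots t_4$ (nominally 0.5, 3, 24,
72 h) are integrated as

$$\int_0^\infty y\,dt \approx t_1 y_1
  + \tfrac{1}{2}(y_1+y_2)(t_2-t_1) + \tfrac{1}{2}(y_2+y_3)(t_3-t_2)
  + y_3 / k, \qquad k = \frac{\ln(y_3/y_4)}{t_4-t_3}.$$

Numerical conventions, each of which was a genuinely open choice:

* **Leading edge.** The first scan follows administration closely; the
  default rule holds the first measured value constant back to $t=0$
  (a rectangle). The alternative (`leadingRule = "zero"`) is available.
  The phantom's first acquisition is deliberately set at 0.5 h so this
  segment is exercised rather than hidden at $t_1 = 0$.
* **Tail anchoring.** The exponential tail passes exactly through $y_3$
  with the rate fixed by the final two points — the unique curve through
  two points, which is what fitting two parameters to two observations
  admits. The $[t_3, t_4]$ interval belongs to the tail, not to a third
  trapezoid.
* **Tail growth guard.** If $y_4 \ge y_3$ (late accumulation, or noise) no
  decaying exponential fits; the physical decay constant of the nuclide is
  substituted — the most conservative physically admissible tail — and the
  fit is flagged. With a saturating uptake process this guard is
  numerically benign: the fitted and fallback rates coincide at the
  boundary.
* **Zero anchor in maps.** A voxel with $y_3 = 0$ and $y_4 > 0$ is
  non-physical for noise-free input and raises an error naming the voxel.
  Sparse Monte Carlo sampling can produce the pattern legitimately, so
  voxel-wise map integration offers a documented `"late_tail"` rule
  (trapezoid over $[t_3,t_4]$ plus a fallback tail from $t_4$).

VOI mean doses use the *VOI route*: the energy-weighted mean dose rate over
the mask at each time point, then the hybrid rule on four scalars. This is
the appropriate estimator for mean VOI doses from Monte Carlo maps: fitting
tails voxel by voxel on low-history maps is upward-biased, because voxels
with noisy, nearly flat $y_3, y_4$ pairs produce arbitrarily small rates
$k$ and arbitrarily large tails. Voxel-wise integration is reserved for
dose maps and DVHs.

Blood and planar series, with seven and four samples respectively, use a
leading rectangle, trapezoids across all samples, and an exponential tail
from the final two samples with the same physical-decay guard.

## Red bone marrow: three competing methods

* **3D LV route.** The lumbar-vertebrae VOI is delineated per time point
  (serial co-registration of the spine is unreliable, so masks are inputs
  per scan); mean dose rates per scan are integrated with the hybrid rule.
  BED is attached as $\mathrm{BED} = AD\,(1 + G(\infty)\,AD/(\alpha/\beta))$
  with $\alpha/\beta$ = 10 Gy and repair rate $\mu$ = 0.46 h^-1^. The
  Lea-Catcheside factor is computed by nested adaptive quadrature of
  $G(\infty) = \frac{2}{AD^2}\int_0^\infty \dot D(t)\int_0^t \dot D(t')
  e^{-\mu(t-t')}dt'\,dt$; the inner integral is evaluated in its shifted
  form to avoid overflow, and the mono-exponential closed form
  $\lambda/(\lambda+\mu)$ serves as the test oracle at 1e-4.
* **Blood route.** Marrow time-integrated activity is the blood
  concentration integral times the marrow-to-blood concentration ratio
  (default 1, the protocol's assumption) times the marrow mass; the
  remainder of body is the whole-body integral minus the marrow term,
  floored at zero with a warning. Dose combines a marrow self S-value and
  a remainder cross S-value.
* **2D cranium route.** Cranium ROI counts are quantified by the
  conjugate-view geometric mean $\sqrt{C_{ant} C_{post}}\,e^{+\mu T/2}$
  with the broad-beam coefficient $\mu$ = 0.13 cm^-1^ and body thickness
  $T$, converted with the calibration factor (6.23e-6 MBq per count),
  integrated over time, and scaled to the whole skeleton by the reference
  cranium marrow fraction 0.119. The remainder cross term is omitted on
  this route, matching the description level of the method it reproduces.

The marrow mass (1170 g) and the S-values are *reference-phantom
placeholders*: the protocol delegates them to external software whose
coefficients are not published. The self S-value defaults to the ^177^Lu
mean beta energy spread over the configured marrow mass with absorbed
fraction 1 (0.0657 mGy per MBq·h at 1170 g); the remainder cross S-value
defaults to a small placeholder (1.1e-4 mGy per MBq·h). Every report embeds
the values actually used, so a site can substitute model-specific
coefficients and the provenance of any reported dose remains visible.

## Tumor dosimetry and the sphere model

The tumor mean dose is the mass-weighted mean of the integrated dose map
over the tumor VOI (or the VOI route for mean-only summaries). The DVH is
the cumulative volume-fraction-at-least curve, 100 uniform bins by default,
whose area recovers the mean dose exactly for the empirical distribution.
The sphere-model comparator computes the VOI mass from the density map, the
tumor time-integrated activity with the hybrid rule, and multiplies by a
sphere self-dose coefficient interpolated log-log from a table generated by
*this package's own engine* (uniform unit-density spheres in a cold
background). Using the same physics for both routes means any difference
between them isolates geometry — the sphere model's isolation assumption —
rather than cross-section differences: with surrounding activity the voxel
route must exceed the sphere model, and the tests assert exactly that
inequality rather than any fixed percentage.

## Matched-pair ^90^Y simulation

An activity series imaged with ^177^Lu is rescaled voxel-wise by
$e^{-(\lambda_{Y} - \lambda_{Lu})t}$ — same administered activity, same
biological kinetics, physical decay swapped — and re-transported with the
^90^Y spectrum. The tumor-to-RBM dose ratio is compared between nuclides;
the percentage difference is computed against the ^177^Lu ratio. The
direction of the effect follows from the integral algebra: a shorter-lived
nuclide suppresses late activity more, so the ratio rises exactly when the
marrow curve is more back-loaded than the tumor curve — the late marrow
accumulation scenario. The package tests this as a direction and as a trend
(larger accumulation, larger gain), never as a fixed number.

# The digital phantom

`phantomSpec()` encodes the emulated study conditions: a 64 × 64 × 48 grid
at 4.795 mm isotropic voxels for tests (the full protocol matrix is
128 × 128 × 78 — the printed "4,795 mm" voxel dimension is read as a
decimal-comma typo for 4.795 mm), acquisitions at 0.5, 3, 24 and 72 h
(the protocol's first scan is "immediate"; 0.5 h is a declared convention,
not an inference), 5600 MBq administered, and three geometric compartments
with biological retention
$r(t) = a\,[f e^{-\lambda_1 t} + (1-f)e^{-\lambda_2 t}] + u(1-e^{-\lambda_u t})$:

* **body** (ellipsoid, 1.0 g/cm^3^): 90% of the administered activity,
  biexponential washout (95% at 0.60 h^-1^, 5% at 0.05 h^-1^) — a fast
  renally cleared peptide;
* **tumor** (sphere, 22 mm radius, 1.05 g/cm^3^): 0.4% uptake, 30%
  clearing at 0.30 h^-1^ and 70% retained at 0.004 h^-1^ — tumor-to-body
  contrast emerges within hours and grows;
* **LV** (vertebral box, 1.30 g/cm^3^, labeled bone by the density
  thresholds): an early blood-tracking pool (0.12% at 0.5 h^-1^) plus a
  saturating marrow uptake term (0.025% amplitude, rate 0.2 h^-1^) — the
  marrow concentration exceeds its surroundings from roughly half a day
  onward, the accumulation pattern visible on late scans.

These magnitudes put the phantom in the cohort's ranges (marrow around
0.9 Gy, tumor around 3 Gy, blood-method marrow around 0.3 Gy at 5.6 GBq)
and were fixed once as study conditions. Activity is uniform within a
compartment (no texture) — the simplest model that still exercises VOI
statistics; overlaps resolve by list order. The truth ledger stores, per
compartment, the exact analytic time integral of the kinetics and the
hybrid-rule integral of the analytic samples, written out independently of
the fitting code, so pipeline tests can separate integration-rule error
from Monte Carlo error. The blood model is a biexponential concentration
curve times physical decay; planar views are attenuated line integrals
through body voxels obeying the conjugate-view identity; toxicity labels
come from a noisy threshold model (0.4 Gy threshold, 0.05 Gy noise, grade
breakpoints 0.55/0.70/0.85 Gy).

What the phantom does *not* emulate — and therefore what passing tests do
not show about real data: SPECT projection/reconstruction physics
(collimator blur, scatter, partial-volume effects, which the original
protocol also left uncorrected), anatomical realism, registration error,
intra-compartment heterogeneity, and inter-patient kinetic variability.

# Numerical choices and problem sizes

* Monte Carlo tests run 1e4–1e5 histories on 20^3^–64 × 64 × 48 grids;
  statistical assertions use binomial counting error or replicate spreads,
  always at three standard errors. The default configuration carries the
  protocol's 1e6 histories.
* The equilibrium oracle, the hybrid-rule oracle (adaptive quadrature of
  the piecewise curve), the Lea-Catcheside closed form, and the local-beta
  sphere closed form are all computed independently of the code paths they
  check.
* Bisection in contour matching runs 60 halvings on the monotone
  count-above-threshold function and flags results that miss the reference
  volume by more than one voxel.
* The engine's RNG is a seeded xoshiro256+ stream, independent of R's RNG,
  so runs are bit-reproducible for a fixed seed across platforms.

# Known limitations

Photon cross-sections are bundled at the few-percent level, adequate for an
engine whose quantitative validation is beta-dominated; bremsstrahlung and
coherent scattering are omitted; ^90^Y electrons travel straight lines;
planar quantification uses a single body-thickness attenuation correction;
the cranium and blood routes inherit reference-phantom S-values unless a
site overrides them. The dose-toxicity threshold that the separation
analysis reports is a descriptive midpoint of the analysed cohort table,
not a clinical recommendation.
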