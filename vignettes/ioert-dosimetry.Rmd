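---
title: "Desk-scale Monte Carlo dosimetry for breast IOERT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale Monte Carlo dosimetry for breast IOERT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioertmc)
```

## The problem

Intraoperative electron radiotherapy (IOERT) delivers a single high dose
(typically 21 Gy to the depth of maximum dose, z~max~) to a surgically
exposed tumor bed through a cylindrical applicator docked onto the tissue.
Treatment planning rests almost entirely on output factors (OFs) — the
ratio of the dose at z~max~ for a given applicator/energy to that of the
reference 10 cm flat applicator at the same energy — measured once during
commissioning. Since those measurements carry appreciable uncertainty, a
tuned Monte Carlo model of the accelerator is a practical cross-check, and
the only realistic way to estimate quantities that cannot be measured in a
patient: out-of-field organ doses, and the consequences of a misaligned
shielding disk beneath the tumor bed.

`ioertmc` implements that whole chain at desk scale: a simplified
condensed-history electron transport engine with a parametric
accelerator-head model, phase-space recording/replay, depth-dose and
profile extraction with detector-volume averaging, gamma-index validation,
iterative source tuning, output factors with uncertainty propagation, and a
MIRD-style anthropomorphic thorax phantom for organ dosimetry.

## The transport model and its assumptions

The engine (C++ via Rcpp) transports **electrons only** in a
condensed-history loop:

* **Energy loss.** Continuous slowing down with collision stopping powers
  interpolated log-log from bundled reference tables (0.1–15 MeV, nine
  materials) and scaled linearly with density. A radiative fraction —
  tabulated from the complete-screening form
  $S_{rad} \approx 0.7\,(E + m_ec^2)/X_0$ divided by the collision
  stopping power — is removed from the electron but *not* transported as
  photons. At 6–12 MeV this under-deposits the small bremsstrahlung
  re-absorption component; it is the engine's main documented bias.
* **Multiple scattering.** A Highland-form Gaussian deflection per step,
  $\sigma_\theta = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{t/X_0}\,
  (1 + 0.038 \ln(t/X_0))$, floored at zero. Large-angle Molière tails are
  not modeled.
* **Stepping.** Steps never cross voxel faces or machine-element
  boundaries; the default maximum step is 1 mm in the phantom (matching
  the 1 mm voxel pitch) and 10 mm in air, with a 20% cap on the fractional
  energy loss per step. Below the 0.2 MeV cutoff the residual energy
  deposits locally — at 1 mm voxels nothing is gained by tracking further.
* **Scoring.** Per voxel: deposited energy (MeV) and the number of
  distinct electrons entering (re-entry after leaving counts again). The
  entry count drives the counting-statistics uncertainty model,
  $\sigma_{rel} = 1/\sqrt{n}$, with zero-entry voxels flagged undefined.
  Energy bookkeeping (injected = phantom + upstream + radiative + escaped
  + wall-absorbed) closes to better than $10^{-6}$ relative on every run
  and is asserted in the test suite.
* **Determinism.** The engine uses a private Mersenne-Twister stream; a
  fixed configuration and seed reproduce the dose grid bit for bit.

Positron and photon transport, neutron production (negligible for these
beams) and detailed ionization physics are out of scope by design.

## The machine model and its calibration

The true accelerator-head geometry is proprietary, so the head is a
*calibrated stand-in*: titanium exit window, tantalum primary scattering
foil, aluminium secondary scattering foil (SSF; density and thickness are
configuration knobs), a primary collimator aperture, and an
absorbing-walled cylindrical applicator (diameter 4–10 cm, bevel 0/15/30°,
optional air gap to the phantom). Applicator walls are perfect absorbers —
no wall scatter re-enters the field, a known fidelity limit that mainly
softens the penumbra.

The free SSF thickness is energy-specific, mirroring heads that insert a
different foil per operative energy, and was calibrated **once** so that
the broad-beam central-axis depth of maximum dose for the tuned spectra
(mean energy / sigma of 7.2/0.7, 9.8/0.9 and 12.35/1.2 MeV for the 6, 9
and 12 MeV beams) lands at the reference depths of 13, 18 and 22 mm with
the reference 10 cm applicator. Those calibrated values ship as the
defaults of `default_machine_stack()` and are not revisited by any test.

## Curves, detectors and z_max

`extract_pdd()` and `extract_profile()` average the dose grid over
detector-like scoring volumes: 1×6×6 mm³ (36 mm³, parallel-plate-chamber
class) for depth-dose curves and 1×3×6 mm³ (18 mm³, diode class) for
profiles, with the 1 mm axis along the scanned direction.
`resample_to_measurement()` reproduces the commissioning sampling scheme:
1 mm steps everywhere except the central flat region of profiles (|x| ≤
0.35 × field diameter), which is sampled at 4 mm and linearly interpolated
back to 2 mm, and the region beyond the depth-dose build-up, sampled at
2 mm.

`find_zmax()` is by default the argmax with ties broken toward the surface.
Because the electron depth-dose peak is a flat plateau relative to
Monte-Carlo point noise, the function also offers 3-point smoothing passes
and an iterated local-parabola refinement (`fit_window_mm`); the package's
own z~max~ quotations use 5 smoothing passes and an 8 mm half-window,
which reproduces the calibration targets to a few tenths of a millimetre
at 4 × 10⁶ histories.

## Gamma analysis and source tuning

`gamma_curve()` implements the 1D global gamma index: for each reference
point the minimum over the evaluated curve (linearly interpolated at
0.1 mm inside a ±3×DTA window) of
$\sqrt{\Delta r^2/\delta^2 + \Delta D^2/(\tau D_{norm})^2}$ with the
clinical 3%/3 mm tolerances, global normalization to the reference
maximum, and no low-dose threshold; γ = 1 counts as passing. The search
window and interpolation step are cost bounds, both configurable; the test
suite checks exact agreement with a dense brute-force minimizer.

`tune_full()` reproduces the iterative commissioning-style procedure:
alternate a grid search over the energy spectrum (steps 0.05 / 0.01 MeV,
gated on the PDD) and over spot FWHM (0.5–8 mm) and divergence (0–5°,
gated on both lateral profiles), first at a 90% pass-rate gate, then
tightening to the 95% final gate until every curve passes or the iteration
budget is exhausted. Candidates are walked outward from the initial value
in rings so that an already-passing initial source is returned unchanged;
each candidate gets a fresh deterministic seed and every engine invocation
is logged with it.

A practical caveat, established empirically with the engine: with 3 mm
distance-to-agreement, a small mean-energy change merely translates the
fall-off by a fraction of the DTA, so the 3%/3 mm gate cannot resolve
spectral shifts much below ~1 MeV at desk-scale statistics — resolving
0.05 MeV steps would require per-point noise near 0.1%, i.e. ~10⁸
histories per candidate. The engine-backed recovery experiments therefore
run the energy search on a 1 MeV grid (the resolution the gate actually
has) with a widened chamber footprint and identical curve smoothing on
reference and candidates, which keeps the per-point noise well inside the
3% tolerance and makes the gate sharply discriminating (truth passes at
~100%, one-grid-step neighbours fall clearly below the 90% gate);
pure search-logic tests use an analytic curve model with tight criteria.

## Output factors

`compute_of()` evaluates OF = D(non-reference)/D(reference) on the central
axis at the energy's frozen reference z~max~ (13/18/22 mm), with the
uncertainty propagated in quadrature from the entry counts. Two readout
modes exist: the default chamber-like 36 mm³ volume and a single-voxel
mode; a wider user-supplied scoring volume (e.g. 2×30×30 mm³) is the
recommended choice for air-gap ratios, where the field is flat on-axis and
counting noise otherwise dominates.

## The synthetic reference generator

`generate_reference_set()` stands in for measured commissioning curves:
an engine run at the truth parameters, detector-volume scoring,
measurement-grid resampling, normalization, and independent additive
Gaussian noise of 2.1% per point — the level of experimental uncertainty
typical of such measurements. Provenance (truth, noise, seed) travels with
the set and regeneration is bit-identical. What the generator does *not*
emulate: correlated detector drift, positioning errors, beam-current
fluctuations, or film-calibration nonlinearity — so a tuning pass on
synthetic references demonstrates the machinery, not robustness to every
systematic a real commissioning data set can contain.
`generate_parametric_pdd()` provides an engine-free closed form (quadratic
build-up joined at the peak to a half-Gaussian fall-off through 100% at
z~max~ and exactly 50% at R50) for unit tests; only those constraints are
contractual. `generate_film_image()` emulates the no-applicator film
exposure as a circular Gaussian fluence map with optional pixel noise.

## The thorax phantom and organ dosimetry

`build_thorax_phantom()` voxelizes a MIRD-style female phantom from
geometric primitives (ellipsoids, cylinders, boxes, shells) in the beam
frame: the surgical-target left breast is a flattened 8 cm disk of tissue
on the beam axis; the trunk is an elliptical cylinder whose midline sits
9 cm to the patient-right; the rib cage is a concentric elliptical shell
so the anterior ribs lie directly beneath the target; lungs, heart and the
remaining table organs are coarse primitives, with distant organs (head,
legs) present mainly so every row of the standard relative-dose table has
a home. Overlaps resolve by a documented priority order (bones and
contained organs over containers; the trunk is the residual soft-tissue
volume). An 8 cm diameter, 1 cm thick copper shielding disk sits beneath
the target by default ("1 cm thick" follows the literal reading of the
source geometry description; both dimensions are configurable).

Numerical choices worth recording: the default organ-scale pitch is 2 mm
(vs 1 mm in the water phantom); flat primitive faces are aligned with
voxel boundaries and voxels are claimed by supersampled occupancy (3×3×3
majority) for organs under 500 cm³, which keeps every organ's voxelized
volume within 2% of its analytic volume; small bone-against-rib-shell
intersections (clavicles, scapulae) are tolerated at the sub-percent
level. Organ masses come from analytic volumes × material density, with
container organs subtracting their contents.

`score_organ_doses()` sums deposits per organ label, converts with
D = E/m, and reports doses relative to the left breast (exactly 100% for
the reference row); `absolute_doses()` scales by the 21 Gy prescription.
`misalignment_study()` runs paired arms (disk present/absent or offset)
with the same seed and tabulates the per-organ differences. Because the
engine transports electrons only, genuinely distant organs receive no dose
at all rather than the tiny photon-mediated dose a full coupled
simulation would show; the package's out-of-field *absolute* numbers for
such organs come from the relative-dose scaling pipeline, not from
transport.

## Problem sizes

The shipped tests and the acceptance script size their simulations so the
whole chain stays desk-scale: 2 × 10⁴ – 10⁶ histories for unit-level
engine checks, 2–3 × 10⁶ per arm for air-gap output factors (with a wide
scoring volume this resolves the ratio to better than 1%), means over
three 2 × 10⁶-history runs for z~max~ quotations (single-run estimator
spread ≈ 0.3–0.7 mm), ten repetitions of 5 × 10⁵ for the spectrum-recovery
experiment, and 4 × 10⁴ on a 4 mm thorax grid for the misalignment
comparisons. The statistical behaviour
(1/√N scaling) is itself asserted in the suite, so these sizes trade only
precision, not correctness.

## Known limitations

* No photon/positron transport: bremsstrahlung energy leaves the problem;
  distant-organ transport doses are structurally zero.
* Perfectly absorbing applicator walls: no wall-scatter component in the
  penumbra, and the head stand-in reproduces calibrated observables
  (z~max~, field width), not the true machine's full phase space.
* Highland small-angle scattering without Molière tails slightly sharpens
  the penumbra.
* The MIRD-style phantom is deliberately coarse; organ doses are
  whole-organ means (no DVHs) and the geometry supports qualitative
  shielding/misalignment conclusions, not patient-specific dosimetry.

## A short tour

```{r tour, eval = FALSE}
machine <- build_machine(default_machine_stack(9), applicator(10, 0))
phantom <- water_phantom(c(16, 16, 8), spacing_mm = 1)
grid <- run_simulation(preset_source(9), machine, phantom,
                       transport_config(5e5, seed = 1))
pdd <- normalize_curve(extract_pdd(grid))
find_zmax(pdd, smoothing_passes = 5, fit_window_mm = 8)
autoplot(pdd)

refs <- generate_reference_set(preset_source(9), machine, phantom,
                               n_histories = 5e5, seed = 2)
glance(gamma_curve(refs$pdd, pdd))
```
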