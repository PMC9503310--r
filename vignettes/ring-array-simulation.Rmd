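---
title: "Methods: simulating an annular ultrasound array for retinal stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating an annular ultrasound array for retinal stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringfus)
```

## The physical problem

A ring-shaped ("racing ring") phased array worn on the cornea focuses
continuous-wave ultrasound through the ocular media onto the retina. The
annular aperture — outer diameter 11 mm, inner diameter 9 mm — leaves a
central hole so the beam bypasses the crystalline lens, whose absorption
(about 7.8 dB at 10 MHz) would otherwise both attenuate the stimulus and
heat the lens. The elements sit on a spherical cap of radius 12 mm matching
the eyeball, and the nominal working point is 20 MHz with a stimulation
plane 7 mm deep (rat retina). `ringfus` simulates this device end to end:
element layout, pressure fields, multi-focus drive solutions, image-to-
pattern holography, and the dose/frequency trade-offs.

All internal lengths are mm, frequencies MHz, times µs; the speed of sound
enters as mm/µs (1500 m/s = 1.5 mm/µs), so at 20 MHz the wavelength is
`wavelength_mm(20)` = 0.075 mm — exactly the one-wavelength element pitch of
the reference design. SI units appear only at the dosimetry boundary
(dB/cm, mW/cm²).

## Array geometry

`build_ring_geometry()` places candidate elements on a square x–y lattice
with the design pitch, keeps those whose lateral radius lies in
[ID/2, OD/2], and projects each onto the cap via the sag
$z = R_c - \sqrt{R_c^2 - r^2}$ (cap apex at the origin, beam along +z,
sphere center at $(0,0,R_c)$). A seeded uniform draw without replacement
then keeps exactly `n_elements` of them. Three choices deserve comment:

* **Point-source elements.** The nominal element (0.15 mm) is wider than
  the lattice pitch (0.075 mm), which would overlap physically. Elements
  are therefore modeled as point sources at the lattice nodes; the element
  size enters only through the radiating area, which scales each element's
  amplitude in the propagator. A square lattice was chosen as the simplest
  layout consistent with a uniform pitch.
* **Sparsity.** "512 elements, ~10% sparse" is read as: keep exactly 512 of
  the full candidate lattice (5604 nodes for the reference design, a 9.1%
  keep fraction, reported as `sparsity_fraction`). The sparsification seed
  is a field of the array specification object and is recorded in every
  export.
* **Areas.** By default every element carries the nominal area
  `element_size²`. The alternative `area_mode = "lattice"` assigns the true
  spherical surface patch per node, `pitch² R_c / \sqrt{R_c^2-r^2}`, so a
  dense (non-sparse) geometry tiles the cap exactly; that mode is what the
  closed-form focused-radiator cross-check uses.

## Forward model

The propagator discretizes the Rayleigh–Sommerfeld integral over point
sources:

$$H_{mn} = \frac{j\rho c k}{2\pi} S_n \frac{e^{-jk d_{mn}}}{d_{mn}},
\qquad P = HU .$$

Conventions that matter:

* **Time/phase.** The harmonic factor $e^{j\omega t}$ is dropped; stored
  phases are $-k d$, so conjugate (+kd) phases focus
  (`conjugate_phase_excitation()`).
* **No obliquity factor.** Elements radiate spherical waves; a cosine
  directivity is deliberately omitted to match the point-source assumption.
* **Attenuation off by default.** Field maps are lossless; the power-law
  attenuation (converted to Np/mm from the medium's dB/cm law) is applied
  only when `attenuate = TRUE`, as in dosimetry pipelines.
* **Scale.** Pressures carry the mixed mm/MHz unit system and are
  meaningful up to a common factor; all reported maps and widths are
  relative (dB re grid maximum).

Correctness is anchored by three independent oracles in the test suite: an
explicitly coded double-loop summation (entrywise agreement to 1e−12), the
exact $1/d$ decay of a lone element, and O'Neil's closed-form focal pressure
of a concave bowl, $|p| = \rho c u k h$ with $h$ the bowl depth — an annulus
being the difference of two caps, a dense lattice-area geometry reproduces
it to well under 2%.

`measure_beam_widths()` finds the global intensity maximum (rejecting peaks
on the grid border) and measures widths along the two grid axes where
intensity crosses the requested level (−3 dB of intensity = FWHM by
default), linearly interpolating between samples; a profile that never
crosses inside the grid is returned as censored (`width >= extent`) rather
than guessed.

## Multi-focus solver

For M prescribed control-point pressures (M ≪ N elements),
`solve_min_norm()` returns the minimum-Euclidean-norm exact interpolant
$\hat U = H^{*t}(HH^{*t})^{-1}P$. The Gram matrix condition number and the
relative residual are always part of the result; a rank-deficient system
falls back to a Tikhonov-regularized solve
($\varepsilon = 10^{-10}\,\mathrm{tr}(HWH^{*t})/M$) with a warning, never
silently. Target phases default to zero; randomizing them is available to
reduce inter-focus interference.

`solve_weighted()` iterates the diagonal re-weighting
$w_n \leftarrow w_n / \max(|u_n|,\varepsilon)$ (mean-normalized), which
drives element amplitudes toward uniformity while each iterate remains an
exact interpolant. Because extreme weights eventually ill-condition
$HWH^{*t}$, iteration also stops as soon as an iterate's relative residual
would exceed `resid_limit` (1e−8), returning the last exact iterate — the
amplitude spread typically falls from ~14 to ~1 before that guard engages.

## Holography

`angular_spectrum_propagate()` is the exact homogeneous-medium propagator:
multiply the 2-D spatial spectrum by $e^{-j\,dz\sqrt{k^2-k_x^2-k_y^2}}$ on
the propagating band and zero the evanescent components. The negative sign
follows from the same $e^{j(\omega t - kd)}$ convention as the
Rayleigh–Sommerfeld operator; the two propagators agree to ~0.2% on a
band-limited source, which the suite verifies against a brute-force kernel
summation. Sampling coarser than λ/2 triggers a warning. The single-
transform Fraunhofer relation (`image_to_aperture()`, with its exact
inverse `aperture_to_image()`) is kept as an initializer/diagnostic: at
7 mm the target plane is not truly far-field, so the angular spectrum is
authoritative.

`gsw_synthesize()` runs the weighted Gerchberg–Saxton loop on a source
plane the size of the target, zero-padded ×2 against wrap-around:

1. propagate the phase-only source to the target plane;
2. on support pixels (target ≥ 10% of its max) replace the amplitude by the
   weighted target, updating weights by
   $w_s \leftarrow w_s \langle|V|\rangle/|V_s|$ (clamped to [1e−3, 1e3]);
   elsewhere in the target block impose the target amplitude (≈ 0
   background), while the padding border keeps its computed values
   (amplitude freedom);
3. back-propagate and restore unit amplitude on the source aperture.

The initial phase is a focusing lens toward the pattern centroid plus a
seeded uniform perturbation (±0.5 rad, seed 1 by default) — deterministic
given the seed.

Two design points were genuinely open:

* **Convergence reporting.** The raw per-iteration support uniformity
  $1 - (\max-\min)/(\max+\min)$ oscillates: the amplitude replacement can
  transiently worsen the spread before the weights absorb it (dips of
  0.03–0.2 were measured under lens, Fourier and random initializations,
  damped or not). A stop-on-first-non-improvement rule would therefore
  terminate after one iteration, and selecting the best-uniformity iterate
  is unsafe — on symmetric point targets a degenerate centroid focus scores
  uniformity ≈ 1 with almost no energy delivered. The loop consequently
  returns the **final** iterate, stops early only when uniformity reaches
  `1 − tol`, and reports `uniformity_history` as the running best (a
  monotone convergence monitor) alongside the raw `uniformity_trace`.
* **Planar vs curved evaluation.** The hologram lives on a plane.
  `sample_hologram_to_elements()` maps each element to its nearest pixel
  and removes the paraxial phase advance $k \cdot \mathrm{sag}$ that the
  element's forward position on the cap would add; the end-to-end check
  (hologram → elements → Rayleigh–Sommerfeld field) lands the focus on the
  requested point to within one pixel. `pattern_pipeline()` supports both
  paths and records which one produced the reported field.

`pattern_quality()` reports zero-mean normalized correlation between the
achieved magnitude and the target, support uniformity, and the fraction of
field energy on the support.

## Dosimetry

Four pure functions with their defaults and units:

* `fwhm_resolution()` — $D_l = K\lambda F_\#$, K = 1, F# = 1 by default;
  0.075 mm at 20 MHz in water.
* `required_pressure_ratio()` — under the bilayer-sonophore strain law the
  peak pressure must grow as $(f_2/f_1)^\beta$ to keep the maximal areal
  membrane strain constant; β defaults to 0.85, the midpoint of the
  published 0.8–0.9 range. Because the printed form of the scaling law is
  typographically ambiguous, the exponent rule is a named strategy
  (`"beta"`, `"half_beta"`, `"inv_two_beta"`) rather than a hard-coded
  constant.
* `attenuation_db()` — $a = a_0 f^\gamma$ dB/cm with vitreous-like defaults
  $a_0 = 0.1$, γ = 1.2 (γ constrained to the physiological 1.0–1.9);
  `calibrate_lens_a0()` fits $a_0$ to a measured through-tissue loss such
  as the lens's 7.8 dB at 10 MHz.
* `safety_power_budget()` — converts the 50 mW/cm² ophthalmic intensity
  ceiling into the maximum power over a square pattern: 40.14 mW for the
  8.96 mm pattern. A stated external budget is checked, not adopted: the
  oft-quoted 80.3 mW requirement over the same area implies 100 mW/cm²,
  and the report flags that inconsistency explicitly instead of resolving
  it.

## Synthetic inputs

Every test input is generated in code (`pattern_recipe()` /
`render_pattern()`): letter rasters from a built-in 5×7 dot-matrix font
(integer block scaling, so pixel counts are exactly re-derivable from the
glyph tables), point sets, disks, checkerboards, and canonical focus
suites (`reference_focus_sets()`). These fixtures emulate the *geometry* of
stimulation targets — binary strokes at the 0.035 mm pattern pitch — but
not the gray-scale statistics, noise, or motion of camera-captured scenes,
nor any tissue inhomogeneity; passing tests therefore validate the numerics
and the synthesis chain, not in-vivo performance.

## Numerical choices and problem sizes

* Tolerances: exact-interpolation residual ≤ 1e−8; operator-vs-oracle
  agreement 1e−12 relative; angular-spectrum round trip 1e−10; closed-form
  focal pressure within 2% (discretization of the cap at 0.02 mm pitch).
* Degenerate inputs fail loudly: empty annulus, infeasible sparsification,
  coincident element/field point, empty GSW support, border peaks and
  censored widths, elements projecting outside a hologram.
* The resolution experiments sample a 1.5 × 1.5 mm lateral plane at 10 µm
  (151² points) at 20 MHz and a 1.5 × 10 mm axial plane at 10 µm at 5 MHz;
  with 512 elements these complete in seconds to tens of seconds on one
  CPU. GSW runs 256×256 targets padded to 512² for 50 iterations in a few
  seconds. Oracle comparisons use 16-element/25-point operators and
  8 × 32 random systems — small enough that the brute-force references stay
  trivially correct.

## Limitations

Continuous-wave, single-frequency, linear propagation in a homogeneous
medium: no pulses, no nonlinearity, no refraction or scattering at ocular
interfaces, no element directivity, no electrical/thickness-mode modeling,
and no neural biophysics beyond the sonophore scaling law. The 1.5 mm focal
widths printed on published field maps are treated as upper bounds: the
diffraction-limited widths this geometry actually produces are an order of
magnitude smaller, and the package measures and reports the latter.
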