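---
title: "Simulating MR-HIFU sonications near biopsy markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MR-HIFU sonications near biopsy markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MR-guided high-intensity focused ultrasound (MR-HIFU) ablates tissue under
continuous proton-resonance-frequency (PRF) thermometry. Patients carrying a
biopsy marker are usually excluded from such treatments because a metallic
implant distorts the gradient-echo images the thermometry depends on.
Whether modern MR-conditional markers (gold, brass, carbon-coated) actually
compromise a breast MR-HIFU treatment is an empirical question with three
measurable faces:

1. how many thermometry voxels the marker's susceptibility void renders
   unreliable (*masked voxels*),
2. whether the marker changes the temperature reached in and at the edge of
   the targeted region, and
3. whether the thermal-dose volume above the ablation threshold
   (240 cumulative equivalent minutes at 43 °C, CEM43) changes.

`sonomark` implements this whole analysis chain — and, because the
underlying phantom experiments require a clinical HIFU system, a synthetic
generator that emulates the images such an experiment produces, so the
chain can be exercised and tested end to end on a desk.

## The synthetic phantom experiment

### Heating

A gel phantom is not perfused, so the bioheat equation reduces to the heat
equation with a deposition source,

$$\frac{\partial T}{\partial t} = D\,\nabla^2 T + a\,s(\mathbf{x}),$$

solved with an explicit finite-difference scheme (FTCS, insulated
boundaries) on an isotropic 1.56 mm grid over a 40 mm cube around the
focus, with a stability guard $\Delta t \le h^2/6D$. The thermal
diffusivity default is 0.14 mm²/s (water-like gel). A perfusion hook
exists (`perfusion_rate_per_s`) and defaults to zero.

The source $s$ is a 3D Gaussian whose −6 dB widths match the transducer's
focal spot (0.7 × 0.7 × 4.5 mm; $\sigma = w / (2\sqrt{2\ln 2})$ per axis),
swept along concentric circles of 3, 6 and 9 mm diameter in the coronal
plane for 30 s at 40 W. Two modelling choices here deserve explanation:

* **Time-averaged sweep.** The focus traverses each circle many times per
  thermal time constant, so the deposition entering the solver is the
  time average of the swept pattern (32 discrete points per circle, time
  shares proportional to circumference). We first implemented a literal
  slow round-robin over 8 dwell points; with a sub-millimetre focus this
  parks the beam long enough to create transient needle hot-spots that
  dominate the field maximum while the quasi-steady pattern stays far
  cooler — the edge of the targeted region then only reaches ~3 °C and
  the 240 EM volume nearly vanishes, which contradicts the documented
  behaviour of this pattern. The averaged sweep restores the intended
  regime: centre peak near 30 °C, edge annulus ~15 °C, ablated volume
  ~0.5 ml.
* **Calibration against the map, not the field.** The heating amplitude
  per watt is not modelled from acoustics; it is calibrated
  (`calibrate_source()`, one simulation plus a ratio, exact by linearity)
  so that the *coronal thermal map* — the 5 mm slab average, which is what
  MR thermometry can actually observe — peaks at 30 °C. Calibrating the
  unobservable 3D point peak instead leaves the map peak near 25 °C and
  every downstream map-based quantity low.

The per-phantom gel absorption varies in reality; `make_phantom_cohort()`
draws absorption factors from a normal law (mean 1, sd 4.6 %, truncated to
[0.8, 1.2]). Temperature rise is exactly proportional to this factor, which
the absorption-correction procedure later exploits.

### Image formation

`render_images()` produces coronal (x, y) and sagittal (y, z) complex
series on the 200 mm / 1.56 mm imaging lattice; both grids use even sizes,
so the sonication centre falls on a voxel corner and voxel centres sit at
half-integer multiples of the pitch — the convention under which the
9→12 mm edge annulus holds exactly 28 voxels. Per frame and voxel:

* **Phase** is a fixed smooth polynomial baseline plus $k\,\Delta T$ with
  $k = 2\pi\gamma B_0 \alpha\, T_E$ = 0.0754 rad/°C at the default
  TE 20 ms, 1.5 T, $\alpha$ = 0.0094 ppm/°C. At that sensitivity a phase
  wrap corresponds to ~83 °C, far beyond the dynamic range, so no
  unwrapping chain is needed beyond wrapping differences to (−π, π].
* **Magnitude** follows the spoiled gradient-echo steady state with
  $T_1(\Delta T) = T_1^0\,(1 + 0.01\,\Delta T)$ — the ~1 %/°C T1 increase
  that makes the signal (hence SNR) drop as the phantom heats. The
  baseline $T_1^0$ defaults to 1800 ms (dilute agar at 1.5 T is long-T1),
  which at TR 85 ms / flip 20° yields a ~15 % signal drop at +30 °C.
* **Noise** is independent Gaussian on the real and imaginary channels
  with sd `1 / baseline_snr` (default SNR 50 against a background
  magnitude normalised to 1; `baseline_snr = Inf` renders noiseless
  data, on which rendering followed by `phase_to_temperature()` is the
  identity to machine precision).
* **The marker void** multiplies the magnitude by a radial suppression
  profile over the marker's *apparent-size* ellipsoid — its physical
  dimensions times the apparent-size factors (cohort means ×4.2 width and
  ×2 length; the Visicoil 1.1 × 10 carries its measured anchors, apparent
  width 3.5 mm parallel to B0 and 6.5 mm orthogonal). The long axis lies
  along B0 (the in-plane axis shared by both views) for `parallel_B0`
  markers and along the slice-normal/vertical axis for `orthogonal_B0`.
  Because the factors were measured on images, the footprint is the
  ellipsoid's mid-slice cross-section and is not re-attenuated through
  the slab (a thin marker would otherwise vanish entirely, contradicting
  its measured apparent width).

All profile variants cross 50 % of background at the apparent boundary, so
the apparent size measured at the conventional 50 % level is
profile-independent. The default profile, however, is not a hard binary
void but a **core + halo** shape: a deep core (5 % of background) inside
~0.3 of the apparent radius, a broad skirt at 20 % of background out to
the boundary, and a smooth recovery. The skirt emulates the partially
dephased rim of a real susceptibility void, whose voxels hover around the
masking threshold — at SNR 50 the skirt's single-frame temperature noise
is ≈1.9 °C against the 2 °C rule. This marginal regime is what produces
the experimentally observed behaviour that a hard void cannot produce at
all (its masked set is constant): frame-to-frame count fluctuation, count
growth by a factor ~1.8–2 during heating, and the strong correlation
between masked count and peak temperature. With a hard or plain Gaussian
profile those dynamics collapse, which is why `"halo"` is the default and
the others remain options.

## Thermometry and absorption correction

`phase_to_temperature()` divides wrapped phase differences by $k$. The
reference phase is the circular mean of all frames acquired during the
10 s pre-sonication delay rather than a single frame (lower reference
noise; configurable). Temporal averaging (`temporal_average()`, default
factor 4) takes non-overlapping block means — complex means for image
series — drops trailing partial blocks, and re-stamps block-midpoint
times. Averaging complex data weights hot (dimmer) frames slightly less,
so averaging-then-converting and converting-then-averaging agree only to
~2 % of the peak during the steepest ramp; the pipeline converts first.
Note that after averaging, a block whose midpoint precedes the sonication
can still contain heated frames, so reference blocks should lie fully
before the delay.

Each phantom's relative absorption is estimated from reference sonications
fired away from the marker: the 3 × 3-voxel ROI mean at end of sonication,
averaged over that phantom's reference runs, divided by the grand mean over
all phantoms (`absorption_correction()`). The coefficients average to
exactly 1 by construction. The corrected PRF coefficient is
$\alpha_\mathrm{eff} = \alpha \cdot c$: converting a phantom's phases with
$\alpha_\mathrm{eff}$ deflates its temperatures by $c$, so a gel that
absorbs 5 % more no longer reports 5 % hotter and phantoms become directly
comparable — on noiseless synthetic data the equalisation is exact. (The
convention is sometimes verbalised as "dividing the PRF coefficient by the
correction"; written as phase-per-degree, division would *amplify* the
absorption difference quadratically, so this package pins the
multiplicative form, which is the one that achieves the stated purpose.)

## Masking, infilling, dose

A voxel's temperature noise follows from its SNR:
$\sigma_T = \sqrt{2} / (\mathrm{SNR}\, k)$, the $\sqrt 2$ because each
temperature is a difference of two noisy phases. Voxels are masked when
$\sigma_T$ exceeds 2 °C on unaveraged frames (equivalently 1 °C after ×4
averaging — the magnitude threshold is identical); the per-sonication
count keeps voxels masked in strictly more than half the frames. The noise
sd is estimated from the four background image corners (pooled MAD) unless
supplied. Before dose processing, masked voxels are replaced by the mean
of their valid 8-connected in-plane neighbours, iteratively for voxels
with no valid neighbour; cross-slice infilling is off because slices are
5 mm.

The two orthogonal maps are fused by a documented deterministic
normalised-product reconstruction,
$T(x,y,z) = T_c(x,y)\,T_s(y,z) / \max(T_\ell(y), \varepsilon)$, with
$T_\ell$ the mean of the planes' shared-line profiles, $\varepsilon$ a
small-denominator guard (5 % of the line peak) and the output clamped to
the planes' range. The scheme is exact for separable fields and stands in
for the scanner vendor's unpublished reconstruction; outputs carry a
`reconstruction = "normalized_product"` attribute. Because two orthogonal
5 mm slabs are *anisotropic* averages of the same field, their shared-line
profiles legitimately differ by ~25–30 % near the ring; the standalone
consistency warning (20 %) is therefore disabled inside the study loop.

Dose uses the standard piecewise CEM43 form
$\sum_i R^{43 - T_i}\,\Delta t_i$ with $R$ = 0.5 at or above 43 °C and
0.25 below, a 37 °C baseline (patient-like processing despite the
room-temperature phantom), accumulation over the sonication *and* the
60 s cooling window, and the ablated volume as the count of voxels above
240 EM times the 1.56 mm³ isotropic reconstruction voxel.

Two printed voxel-counting conventions coexist deliberately: the edge
annulus (28 voxels) comes from centre membership with a strict inner and
inclusive outer bound, while the 12 mm targeted-region budget (46 voxels)
is the area quotient $\lfloor \pi (d/2)^2 / \Delta x^2\rfloor$ — centre
counting gives 45 or 52 depending on lattice offset and cannot reproduce
46. Both are exposed as separate functions.

## The study driver

`run_study()` wires the stages together: one calibrated base simulation
(every phantom's field is an exact rescaling by its absorption factor, by
linearity), `n_reference` marker-free renders per phantom for the
correction, then `n_on_marker` marker-centred sonications per phantom with
per-sonication metrics (majority masked count against the marker's
cylinder/sphere model volume, maximum unmasked rise under the σ rule, edge
annulus mean at end of sonication, 240 EM volume) and Welch two-sided
t-tests against the marker-free reference phantom with 0.05/0.01/0.001
star coding. Every artifact records the package version, a configuration
hash and the seed; identical seeds reproduce byte-identical CSVs. The
per-frame masked-count and peak-rise curves are averaged over the marker
sonications before correlating, mirroring how such count–temperature
coupling is normally reported (per-sonication correlations are also in the
metrics table).

## Problem sizes and what the tests show

The test suite runs miniature studies (6 s sonication, ~20 mm simulation
cube, 100 mm field of view) plus one full-length study (30 s + 60 s
cooling, 40 mm cube, 0.5 s frames) for the end-to-end checks; the
acceptance script runs the full-length two-marker study. These sizes keep
a complete run in tens of seconds while preserving the grid, voxel and
timing conventions of the full geometry.

Passing tests show that the *analysis chain* is correct (closed forms,
round trips, masking rules, dose arithmetic) and that it reproduces the
generator's design conditions. They do not validate the generator against
real scanner data: the synthetic images have a polynomial static phase
(no B0 drift or motion), Gaussian channel noise (no EPI ghosting or
structured artifacts), a parametric void (no true dipole field), and no
viscous heating at wire surfaces. Quantities tied to real hardware — the
absolute masked counts per marker model, thermocouple agreement slopes,
the measured 0.64 ml reference dose volume — are emulated in regime, not
asserted numerically.

## Known limitations

* The FTCS solver is first-order in time and the 1.56 mm grid
  under-resolves the 0.7 mm focal Gaussian; this is acceptable because
  the deposition is spatially integrated by the sweep and calibration
  absorbs the discretisation constant.
* The normalised-product reconstruction is exact only for separable
  fields; for the ring-heated field it biases the off-plane volume
  (the pipeline's 240 EM volume runs ~10–25 % below the design
  ellipsoid, within the tolerance the package asserts).
* Absorption correction with small cohorts (3 phantoms in the default
  study) estimates each coefficient from few sonications; the cohort-mean
  constraint makes the coefficients exact on average but individually
  noisy at the ~0.5 % level.
* One catalogue ambiguity: the marker documentation does not identify
  which of the five Visicoil markers is the brass one; the catalogue
  records all five as gold.
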