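---
title: "Models and methods behind phasetomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasetomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasetomo)
```

phasetomo implements a complete, self-contained model of single-distance
propagation-based X-ray phase-contrast tomography (XPCT) of stained soft
tissue: the optical-constant arithmetic that links heavy-atom stain
concentrations to image contrast, a parallel-beam Fresnel forward model
with realistic detector defects, the standard projection-domain
corrections, two single-distance phase-retrieval filters, Ram-Lak filtered
backprojection, and the histogram-based workflow that converts the excess
attenuation of a stained sample into a stain atom number density. Because
no raw tomograms of the original experiments are publicly available, every
quantitative claim the package makes is validated in closed loop on
synthetic phantoms whose ground truth is known exactly.

## X-ray optical constants

A material's refractive index for hard X-rays is
$n = 1 - \delta + i\beta$. For a single stain element present at number
density $\rho_a$ (atoms/nm$^3$), the two parts follow from the atomic
scattering factors $f_1 \approx Z + f'$ and $f_2 = f''$ (forward-scattering
convention):

$$\delta = \frac{r_0 \lambda^2}{2\pi} \rho_a f_1, \qquad
  \beta = \frac{r_0 \lambda^2}{2\pi} \rho_a f_2,$$

with $r_0$ the Thomson scattering length and $\lambda = hc/E$. The package
uses $hc = 12.39842$ keV Å and $r_0 = 2.82\times 10^{-15}$ m (the rounded
literature value, overridable via `options(phasetomo.r0_nm = )`).
Attenuation and $\beta$ are related by $\mu = 4\pi\beta/\lambda$, so an
excess attenuation $\Delta\mu$ attributable to the stain inverts to

$$\rho_a = \frac{\Delta\mu}{2 r_0 \lambda f''},$$

and further to a mass density $\rho = \rho_a A / N_A$ and a Wigner–Seitz
mean interatomic distance $d = (3/(4\pi\rho_a))^{1/3}$. All internal units
are keV, nm, atoms/nm$^3$; conversions happen only at interfaces
(`fresnel_number()` takes mm distances because that is how beamline
geometries are quoted).

```{r}
fresnel_number(650, 149, 16)     # the working geometry, F ~ 0.0366
mean_distance(0.0117)            # nm, at a typical stain density
```

The ratio $\delta/\beta = (Z + f')/f''$ decides how well an element suits
phase-contrast imaging: a high ratio gives strong phase shift at modest
absorption, which is also the regime in which homogeneous-object phase
retrieval is best conditioned. `delta_beta_ratio()` evaluates it from a
scattering table; `delta_beta_scan()` tabulates it for plotting.

### Bundled scattering tables are synthetic

The package ships representative $(E, f_1, f_2)$ tables for Nd, Os, U and
I over 2–50 keV (`stain_table()`). They are generated by a per-shell
absorption model — edge jumps at the L and M edges with power-law decay
between edges, anchored at literature-scale magnitudes — with $f_1$
obtained from $f_2$ by a numerical Kramers–Kronig transform plus the
relativistic correction. They reproduce the qualitative structure that
matters here (edge positions, magnitudes, and the ordering of
$\delta/\beta$ ratios between elements, in particular neodymium's
advantage over uranium above the U L$_3$ edge at 17.2 keV) but are *not*
measured optical constants: K-shell structure inside the tabulated range
is not modeled, and absolute values carry tens-of-percent uncertainty.
The closed-loop quantification below is insensitive to this because the
same table is used in the forward simulation and in the inversion. Any
analysis of real data should load a measured tabulation through
`read_scattering_table()`, which also accepts the Henke `.nff` dialect.

A deliberate diagnostic: published pairs of excess attenuation and number
density can be audited with `implied_f2()`, which back-solves the
quantification relation. For the reference pair
($\Delta\mu = 1.8250\times10^{-4}$/vox at 650 nm voxels, 13.8 keV,
$\rho_a = 0.0117$/nm$^3$) it returns $f'' \approx 47$, an order of
magnitude above any tabulated Nd value at that energy — the conversion
behind such published densities evidently used a different $f''$ scale
than standard tabulations, so the package never uses that pair as a
numerical test of the conversion chain itself.

## Phantoms and the forward model

`make_layer_phantom()` builds nested concentric shells (spheres, or
cylinders coaxial with the rotation axis) with per-layer $(\delta,
\beta)$, optionally speckled with small "cell" inclusions.
`retina_phantom()` provides a five-layer eye-like default (sclera,
choroid, rods and cones, nuclear/plexiform, ganglion; 256³ voxels of
650 nm) in which the stain-targeted layers either get a fixed
$\delta/\beta = 5$ coupling (unstained tissue uses 35, the values used for
retrieval of real stained/unstained samples at 16 keV) or the physical
$(\delta, \beta)$ increments of a stated stain density.

The forward model is the standard projection (thin-object) approximation:
line integrals of $\delta$ and $\mu$ through the rotated volume (bilinear
sampling about the central vertical axis) form the exit wave
$t = \exp(-\mathrm{OD}/2 - i\varphi)$, which is propagated by the Fresnel
transfer function $H(\nu) = \exp(-i\pi|\nu|^2/F)$ in reduced frequency
units (cycles/pixel), parameterized solely by the Fresnel number
$F = \mathrm{px}^2/(z\lambda)$. Fields are edge-replicated to twice their
size before the FFT and cropped afterwards; with `pad = FALSE` the
transform is exactly unitary, which the test suite exploits. Multiple
scattering, partial coherence, source blur and cone-beam magnification
are not modeled; a laboratory-style polychromatic acquisition is
represented only as a monochromatic scan at an effective energy.

`simulate_detector()` adds the defects the preprocessing stage must
undo: scaling to photon counts, static per-column gain factors (drawn
once per stack; these become ring artifacts after reconstruction),
Poisson counting noise, additive dark counts, and a seeded set of hot
pixels. Defaults — $5\times10^4$ photons/pixel flat-field level (about
the full well of a 16-bit camera), $2\times10^{-4}$ hot-pixel rate, 0.5%
column-gain spread, 10 flats and darks — were fixed once as plausible
synchrotron microtomography values; the acquisitions they emulate do not
state photon counts. All randomness flows from explicit integer seeds,
and identical seeds give bit-identical stacks.

## Projection-domain corrections

* `flat_dark_correct()`: $(I - \bar D)/(\bar F - \bar D)$, floored at a
  small positive value; shared static gain structure divides out.
* `repair_hot_pixels()`: flags pixels deviating from their 3×3
  neighborhood median by more than `k_mad` (default 10) times the global
  MAD of those deviations, replacing them by the mean of their valid
  8-neighbors. The MAD is taken over the deviation image because that is
  the statistic being thresholded.
* `find_rotation_axis()`: cross-correlates projections at $\theta$ with
  the mirrored projection at $\theta + 180°$; the correlation peak sits at
  twice the axis offset and is refined by a parabolic fit, with the
  median over several pairs reported. Axis-correction algorithms are
  rarely reported alongside tomographic datasets; mirrored
  cross-correlation is the standard choice for full-turn parallel-beam
  data.
* `ring_filter_waveletfft()`: the combined wavelet–FFT stripe filter
  (Münch et al. 2009). The sinogram is wavelet-decomposed along the
  detector axis (Daubechies-25, 4 levels by default), each detail band is
  Fourier transformed along the angle axis, and the stripe energy on the
  zero-angular-frequency line is damped by a Gaussian notch of width
  $\sigma = 2.4$ px. Since no wavelet package ships with R, the package
  implements a periodized orthogonal DWT directly, generating Daubechies
  filters of any order up to 25 by spectral factorization; the test suite
  verifies the db2 closed form and orthonormality at order 25. Note that
  for a perfectly centered, circularly symmetric object the sinogram is
  itself constant along the angle axis, so a small fraction of true
  object detail is treated as stripe; on the validation phantoms this
  biases band-interior attenuation by well under a percent.

## Phase retrieval

Both retrieval filters work in reduced units with
$\chi(\nu) = \pi|\nu|^2/F$ and assume a homogeneous object (fixed
$\delta/\beta$):

* **CTF** (`ctf_retrieve()`): the linearized contrast transfer relation
  gives $\hat{I} - \hat{1} = 2(\sin\chi + \cos\chi/(\delta/\beta))
  \hat\varphi_w$; inversion uses the two-band Tikhonov form
  $\hat\varphi = \hat{C}\,D/(D^2 + \mathrm{reg})$ with
  $D = 2(\sin\chi + \cos\chi/(\delta/\beta))$, where `reg` is `reg_low`
  below the first maximum of $|\sin\chi|$ ($|\nu|^2 = F/2$) and
  `reg_high` above.
* **Paganin** (`paganin_retrieve()`): the single-material low-pass
  $-\tfrac12(\delta/\beta)\ln \mathrm{IFT}[\hat I/(1 +
  (\delta/\beta)\chi)]$, which matches the CTF filter in the small-$\chi$
  limit and is the method used for laboratory data.

Sign and offset conventions: retrieved maps are returned in the
*optical-thickness* convention (positive where material adds phase
delay, i.e. equal to the projected phase $2\pi/\lambda \int\delta\,dz$ up
to the undefined constant), and the mean is set to zero. The default
regularization weights (`reg_low` $= 10^{-3}$, `reg_high` $= 10^{-1}$)
suit noisy data; they act like a noise prior, and for noiseless
closed-loop validation the suite uses $10^{-5}/10^{-2}$, where CTF
inversion recovers weak-phantom projected phase with a normalized RMSE of
a few per mille. With the default weights and $\delta/\beta = 35$ the
low band is deliberately damped by roughly 20% — the price of stability
when real noise is present.

`estimate_fresnel_number()` verifies $F$ from data: the radially averaged
power spectrum of a (weakly scattering, broadband) hologram oscillates
with the CTF, with minima near $|\nu|^2 = mF$. The estimator whitens the
radial spectrum with a running median, locates minima near their expected
positions in two passes (a coarse pass on the first three orders
recenters the windows, which keeps the fit stable when the prior is off
by ±15%), refines each by a quadratic fit, and least-squares fits
$\nu_m^2 = mF$ through the origin. The result is clamped to ±20% of the
prior, and a flat input returns the prior with a warning attribute.
Layered phantoms alone are poor calibration objects — their own spectra
oscillate — so the validation uses speckle phantoms, and the estimator
accepts a stack of frames whose spectra it pools.

## Reconstruction

`fbp()` implements parallel-beam filtered backprojection: each sinogram
row is filtered with the band-limited spatial-domain Ram-Lak kernel
(evaluated via FFT on 2×-zero-padded rows; the discrete kernel rather
than the naive $|\nu|$ ramp, which would misweight DC and bias
reconstructed values by several per cent), then backprojected with linear
interpolation. Full-turn data are backprojected with uniform weight
$\pi/n_\mathrm{proj}$ — each line direction is simply measured twice —
which is robust to residual axis error. Volumes are reconstructed slice
by slice (`reconstruct_volume()`), with the rotation-axis shift applied
by resampling and the ring filter applied per sinogram. Attenuation
volumes carry per-voxel units (1/vox); dividing by the voxel size in nm
gives 1/nm, which is what the density conversion expects.

## Stain quantification

The workflow follows the histogram-comparison recipe used for
stained-tissue tomograms: median-filter the
projections (8×8 window by default; the even window is anchored to the
top-left pixel of its central 2×2 block) so that the oscillating Fresnel
fringes cancel and the projection is absorption-dominated, take
$-\ln I$, reconstruct, histogram a rectangular ROI in a reconstructed
slice for the stained and the unstained sample, take the peak of the
Gaussian-smoothed histogram for each (`roi_histogram()`, ties toward
lower attenuation), subtract (`peak_subtract()`), and convert
(`quantify_stain()`), recording the $f''$ value and its provenance in
the report.

A geometric caveat of the suppression step: an $N\times N$ median removes
edge-diffraction lobes only when the first lobe ($\approx 1/\sqrt{F}$
pixels wide) fits within about half the window. At the deeply holographic
working point ($F = 0.0366$, lobes ~5 px vs. the 8-px window) residues
persist within a few pixels of sharp material boundaries — the
quantification ROI therefore keeps a margin away from layer edges — while
at $F = 0.188$ the 8×8 window meets the intended contract on a sharp
absorbing edge (monotone post-filter profile to within 1% of the step).

Two estimator parameters deserve comment. The histogram defaults
(`bin_width` $= 10^{-5}$/vox, `smooth_sigma` = 2 bins) correspond to the
published real-data histograms, where the peak separation is of order
$10^{-4}$/vox. The synthetic closed loop operates at an order of
magnitude smaller $\Delta\mu$ (its $f''$ scale is the tabulated one, see
above), so the validation uses finer bins and `smooth_sigma = "auto"` (a bandwidth
of three ROI standard deviations); for a unimodal noise-broadened ROI
this makes the smoothed-histogram peak behave like a robust location
estimate rather than hunting individual noise lumps. (A narrow Silverman
bandwidth is the textbook density-estimation choice, but on the strongly
spatially correlated reconstruction noise it leaves the argmax wandering
within the bulk of the distribution.) `quantify_stain()` can also pool or average a
slab of slices (`slab`, `slab_mode`); averaging along z is appropriate
for the cylindrical validation phantom, whose slices cross identical
material.

## The closed-loop validation experiment

`closed_loop_quantification()` packages the end-to-end check: a
cylindrical three-layer phantom (unstained tissue shell, a broad stained
"retina" band carrying 0.012 Nd atoms/nm³ via the physical
$(\delta,\beta)$ increments, unstained core) is scanned — stained and
unstained samples separately, as in the real protocol — at 13.8 and
16 keV, 180 projections over 360° at 256² in-plane voxels, with default
detector noise; the full correction + suppression + FBP + histogram
chain then recovers the stain density at each energy. The cylindrical
geometry (rather than the spherical default) lets the ROI pool a z-slab
of identical cross sections, and its rationale is purely statistical:
at the tabulated $f''$ scale the stain adds only
$\Delta\mu \sim 1.2\times10^{-5}$/vox, so the desk-scale experiment needs
every independent voxel it can get. The ROI keeps a few-pixel margin from
the band boundaries, where median-filtered fringes leave residues.
Problem sizes: the interactive default is 256×256×64 voxels with 180
views (a few minutes for the two-energy experiment); the validation runs
in the test suite and the acceptance script use a 128-slice slab (about
ten minutes), at which point the recovery error is a few per cent,
limited by counting statistics propagated through the reconstruction —
not by the model — and still shrinking with slab height.

What passing this loop does and does not show: it validates the entire
numerical chain — geometry, propagation, corrections, reconstruction
normalization, histogram logic, unit conversions — under Poisson noise,
hot pixels and ring-producing gain errors. It does not probe effects the
forward model excludes (beam hardening, scatter, partial coherence,
detector PSF), nor the accuracy of the synthetic scattering tables, which
cancel in the loop, nor spatial heterogeneity of real stain uptake.

## Numerical choices and degenerate inputs

* FFT grids are zero-centered in wrap-around order; the DC component of
  retrieved phase maps is set to zero by convention.
* Even median windows use a documented half-pixel anchor; borders use
  truncated windows.
* Histogram peak ties break toward lower attenuation; `peak_subtract()`
  flags negative differences rather than clipping them.
* Empty phantoms, flat holograms, and degenerate flats (equal to darks)
  are rejected or returned with explicit warnings rather than producing
  NaNs; `rho_a = 0` short-circuits the mean-distance formula.
* The Daubechies generator is exact for db1/db2 and numerically
  orthonormal to ~1e-9 at order 25 (spectral factorization via
  `polyroot`).

## Known limitations

* The forward model is monochromatic, parallel-beam and noise-limited;
  laboratory cone-beam geometry is represented only through an effective
  pixel size and Fresnel number.
* Scattering tables are synthetic stand-ins (see above) and omit K-edge
  structure within 2–50 keV (Nd K at 43.6 keV, I K at 33.2 keV).
* The histogram-peak estimator assumes the ROI is dominated by one
  material; strongly multimodal ROIs should be split.
* On-disk TIFF stores 32-bit fixed point in an affine range recorded in
  the JSON sidecar (exact to ~1e-9 of the range); HDF5 containers are
  not supported.
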