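# phasetomo

Simulation and quantitative analysis of single-distance propagation-based
X-ray phase-contrast tomography (XPCT) of heavy-atom-stained soft tissue,
in R.

XPCT derives contrast from free-space Fresnel diffraction of the phase
shift that tissue imprints on a coherent X-ray beam. Heavy-atom stains
(neodymium acetate, uranyl acetate, osmium tetroxide, iodine) boost both
the phase shift and the absorption of the tissue they bind to; which
element is best suited for *phase* contrast is governed by its
$\delta/\beta = (Z + f')/f''$ ratio. Once a stained and an unstained
sample have been reconstructed in absorption units, the stain
concentration itself is measurable: the difference of the attenuation
histogram peaks, $\Delta\mu$, converts to an atom number density

$$\rho_a = \frac{\Delta\mu}{2\,r_0\,\lambda\,f''},$$

and onward to a mass density $\rho_a A/N_A$ and a mean interatomic
distance $(3/(4\pi\rho_a))^{1/3}$.

The package is aimed at beamline and lab-CT practitioners who want a
tested, self-contained reference implementation of that workflow — and at
method developers who need a synthetic test bench with exact ground truth.
It provides:

* **optics** — wavelength/Fresnel-number arithmetic, scattering-factor
  tables with interpolation, $\delta/\beta$ scans, and the
  $\mu \to \rho_a \to \rho \to d$ conversion chain
  (`fresnel_number()`, `stain_table()`, `number_density_from_mu()`, ...);
* **simulate** — layered eye-like phantoms and a parallel-beam Fresnel
  forward model with Poisson noise, hot pixels and ring-producing
  per-column gain errors (`retina_phantom()`, `simulate_scan()`);
* **preprocess** — flat/dark normalization, hot-pixel repair,
  rotation-axis estimation, wavelet-FFT ring filtering
  (`flat_dark_correct()`, `ring_filter_waveletfft()`);
* **phase retrieval** — single-distance CTF and Paganin filters plus
  Fresnel-number self-calibration from hologram power spectra
  (`ctf_retrieve()`, `paganin_retrieve()`, `estimate_fresnel_number()`);
* **reconstruct** — Ram-Lak filtered backprojection, slice-wise volume
  assembly (`fbp()`, `reconstruct_volume()`);
* **quantify** — median-filter phase suppression, ROI histograms, peak
  subtraction and density conversion (`quantify_stain()`), with broom-style
  `tidy()`/`glance()` and `autoplot()` methods;
* **pipeline** — YAML-configured workflows (`run_simulate()`,
  `run_reconstruct()`, `run_quantify()`) and a thin CLI
  (`inst/cli/phasetomo`) with subcommands `simulate`, `reconstruct`,
  `quantify`, `optics`.

The bundled Nd/Os/U/I scattering tables are **synthetic** (a per-shell
edge model with Kramers–Kronig-consistent $f_1$; filenames and docs say
so); load measured tabulations with `read_scattering_table()` for real
data.

## Worked example

Simulate a stained and an unstained sample, push both through the full
correction + reconstruction chain, and recover the stain density:

```r
library(phasetomo)

fresnel_number(650, 149, 16)
#> [1] 0.03659267        # the holographic working point, F ~ 0.0366

res <- closed_loop_quantification(
  energies = c(13.8, 16), stain_density = 0.012,
  shape = c(256, 256, 64), n_projections = 180, seed = 1)
res$summary
#> # A tibble: 2 × 5
#>   energy true_density recovered_density  delta_mu rel_error
#>    <dbl>        <dbl>             <dbl>     <dbl>     <dbl>
#> 1   13.8        0.012            0.0127 0.0000180    0.0604
#> 2   16          0.012            0.0122 0.0000120    0.0192

tidy(res$reports[["16"]])
#> # A tibble: 1 × 7
#>   element energy  delta_mu f2_used number_density mass_density mean_distance
#>   <chr>    <dbl>     <dbl>   <dbl>          <dbl>        <dbl>         <dbl>
#> 1 Nd          16 0.0000120    3.45         0.0122      0.00293          2.69
```

`delta_mu` is the stained-minus-unstained histogram peak difference in
attenuation per voxel (1/vox at 650 nm voxels); at 16 keV the tabulated
Nd $f'' = 3.45$ converts it to `number_density` in atoms/nm³, recovered
here within a few per cent of the simulated truth at both energies
(+6.0% and +1.9%; the error shrinks with the slab height). The
`mean_distance` of ~2.7 nm says how sparsely the stain atoms sit in the
stained tissue band.

Element selection for phase contrast:

```r
sc <- delta_beta_scan(lapply(c("Nd", "U"), stain_table))
plot_delta_beta_scan(sc)   # Nd's ratio exceeds U's above the U L3 edge
```

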