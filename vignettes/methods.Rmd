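---
title: "Quantifying condensate–cytoskeleton structural correlations and interfacial adsorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate–cytoskeleton structural correlations and interfacial adsorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Stress granules are liquid-like protein–mRNA condensates that form in the
cytoplasm under stress. Microtubule networks are denser in their vicinity,
and when microtubules are depolymerized the tubulin sub-units accumulate in a
narrow zone at the granule surface. `granuleface` implements a statistical
method for measuring such structural correlations in 3D confocal stacks of
micropatterned cells, and a thermodynamic model that interprets the measured
surface enrichment as non-specific (Pickering-type) adsorption of particles
to a diffuse droplet interface.

The pipeline has seven stages: `simulate` (synthetic scenes), `prep` (cell
detection, QC, alignment, intensity normalization), `detect` (granule
detection by a multi-threshold quality-factor sweep), `reference` (ensemble
reference cell), `correlate` (distribution maps, `g(r)`, `g_s(d)`),
`partition` (per-granule partition coefficients), and `fit` (the robust
one-parameter adsorption-model fit). `run_pipeline()` executes any prefix of
this chain.

# Image analysis

## Cell preparation

Cells are plated on stadium-shaped micropatterns, so every cell has nominally
the same footprint. The footprint is detected as the largest connected
component of the sharpened, Otsu-thresholded overlay of the per-channel
maximum projections; the cell base height `z_b` is the slice of maximum
positive gradient of the per-plane median + 80th-percentile profile of the
filament channel. Cells are discarded when the footprint area falls outside
85–110% of the nominal pattern area, when the principal-axis ratio leaves
[0.43, 0.55], when the orientation deviates more than 3° from the batch
mean (circular mean mod 180°), when the brightest slice is not 2–4 slices
above `z_b`, or when fewer than 10 cells survive in a batch. Survivors are
rotated to horizontal, centred on a common canvas, and flipped so the nucleus
centroid lies in the left hemisphere. Each channel is normalized by its mean
intensity over representative voxels (inside the cell, outside the nucleus,
slices `z_b + 2 … z_b + 4`); voxels outside the cell or inside the nucleus
are masked from that point on. Every downstream statistic reads intensities
through `stack_values()`, which enforces the masked-voxel contract.

## Granule detection

After subtracting a dynamic background (30 × 30 × 5 box mean) and a light
Gaussian smoothing (σ = 1 px), 101 thresholds are probed between the maximum
per-plane mean and the global maximum. Each level's 3D connected components
(26-connectivity) are scored by a quality factor Q combining three criteria
with equal (configurable) weights: stability of the blob count between
neighbouring levels, large mean blob volume, and large median blob volume.
The volume criteria saturate at the volume of a diffraction-limited sphere of
radius 3 px and score zero above a maximum plausible granule volume, so Q has
an absolute scale: percolating components at too-low thresholds and speckle
at high thresholds both score low, and a minimum-quality cutoff can reject
cells with no real granules. The cutoff default (0.8) was calibrated on pure-noise
fixtures, which reach Q ≈ 0.5–0.67, while cells with granules plateau at
Q ≈ 1. Within a tied plateau of maximal Q the chosen level is the lowest one
whose boundary voxels lie in the sharp-gradient zone (at least 90% of the
maximal boundary-gradient magnitude): granules must be set apart by a sharp
edge, and the lower edge of that zone captures the full granule without
overestimating the threshold. In practice this places the detected outline
within about ±1 px of the true surface on synthetic scenes.

Blobs are discarded when the intensity-weighted centroid moves more than
0.5 px upon dilation with a 3-px sphere, when dilations of two blobs fuse,
when the centroid lies outside the cell footprint or inside the nucleus, or
when the effective radius `R_SG = sqrt(A_SG/π)` is below the 3-px (195 nm)
diffraction floor. Per-channel 221 × 221 px crops are taken at the plane
nearest the centroid. After reference normalization, granules less than
twice as bright as their local environment (disc-8 dilation minus the shape)
and positive outliers above the ensemble mean + 1 SD are discarded.

## Reference cell and relative intensities

The reference cell is the voxel-wise mean over all aligned, normalized cells
(each blurred in-plane with a Gaussian of variance 4 px², i.e. σ = 2 px —
the phrase "variance of 4 pixels" is ambiguous and σ is configurable),
re-sliced so slice 1 is each cell's own base height, with each cell
contributing twice through folding across the long-axis centre line. A voxel
is valid only where more than half the contributors are unmasked, and only up
to 1.2 µm (six slices) above the base. A granule's own cell is not excluded
(configurable); with tens of cells the self-contribution is a percent-level
effect. Crops divided point-wise by the matching reference crop are in
relative-intensity units, where 1 means "as expected at that location".

`g(r)` averages relative intensities over all contributing pixels of all
crops at each 1-px radius bin (not over the map), so varying per-pixel
contributor counts are weighted correctly; the standard error is SD/√n per
bin. `g_s(d)` uses the signed minimal Euclidean distance to the detected
outline in the centroid plane (2D distance transform; negative inside),
also in 1-px bins. The computational negative control re-extracts both
channels at the same aligned location in a uniformly chosen *different* cell;
its maps fluctuate around 1 with no surface ring.

## Partition coefficients

For each eligible granule (`R_SG ≥ 0.59` µm and at least three `g_s` entries
at `d ≤ −0.39` µm), the gradient anchor `d*` is the position of maximal
|slope| of the granule-marker `g_s(d)`; the surface level `I_s` is the
maximum of the tubulin `g_s(d)` within ±2 px of `d*`; the bulk level `I_g`
is the mean for `d ≤ −0.39` µm excluding the single most-negative entry (the
granule centre has poor statistics); the cytosol level `I_c` is the mean over
`d ∈ [0.39, 0.52]` µm. Then `k_g = I_g/I_c`, `k_s = I_s/I_c`, and the
affinities are `ln k_g` and `ln k_s` in units of `k_BT`. Using `I_c` close
to the granule, rather than the reference value of 1, makes the coefficients
robust against residual long-range intensity structure. All window constants
are config keys with these defaults.

# The adsorption model

Energies are carried in `k_BT` (temperature default 310 K, configurable;
conversions to SI only at the interfaces). For a sharp interface, the bulk
affinity of a particle of surface area `A0` is `−ΔG_g = −A0 Δγ` with
`Δγ = γ_tg − γ_tc`; a neutrally wetting particle covering interface area
`Ax` binds with `Ax γ_cg`, and the general spherical branch is the classical
detachment energy `π R² γ_cg (1 − |Δγ/γ_cg|)²`, zero beyond full wetting.

For an interface of finite half-width `w` and a particle small compared to
`w`, the energy landscape expanded about the interface centre is

`ΔG(x) = A0 (Δγ/2)(1 − x/w) − V0 (3/2)(γ_cg/w)(1/2 − x²/w²)`,

valid for `|x| < w`; outside, the bulk values apply (the quadratic itself
does not reach the bulk value at `x = +w`, a known property of the
second-order expansion, so the implementation clamps at the boundary).
Its minimum is at `x_eq = A0 w² Δγ / (6 V0 γ_cg)` and the corresponding
surface affinity obeys the one-parameter relation

`−ΔG_s = a0 + (1/2)(−ΔG_g) + (−ΔG_g)²/(32 a0)`,

with `a0 = (3/4) V0 γ_cg / w`, which for a sphere of radius `R` equals
`π R² γ_cg (R/w)`. Both identities are verified against brute-force 1D
minimization over random models to 10⁻⁶ relative. A Boltzmann sampler
(`sample_interface_positions()`, inverse-CDF on a dense grid) provides an
independent stochastic oracle for the landscape.

The inverse estimate `γ_cg = affinity · k_BT / Ax` converts the observed
neutral-point surface affinity (≈0.1 k_BT over ≈25 nm²) into an interfacial
energy (≈15 µJ m⁻² at the nearest-5 precision); because a single sub-unit is
the smallest plausible adsorbing unit, this is an upper bound. Filament-scale
adhesion is linear in length: with 500 contacting sub-units per µm at
0.1 k_BT each, 50 k_BT µm⁻¹ (the sub-unit spacing ν is an explicit parameter;
the printed scaling does not fix the sub-unit geometry). The condensation
pressure `p_cond = n_L k_BT ln(n/n_sat)` and the unbounded-cavity criterion
`p_cond > 5E/6` are provided for context.

`fit_a0()` fits the one-parameter relation to the per-granule
`(ln k_g, ln k_s)` scatter with bisquare-weighted IRLS (tuning constant
4.685, MAD scale; no installed package offers robust *nonlinear* regression,
and the robust fit is part of the method itself). Uncertainty comes from
residual resampling: each point is replaced by its theoretical prediction
plus Gaussian noise with SD equal to the initial-fit residual SD, the fit is
repeated 1,000 times, and the mean ± SD over realizations is reported.
`tidy()` and `glance()` return the results in broom style.

# The synthetic-scene generator

The generator defines the study conditions for every recovery test. It
renders stadium-shaped cells — the experimental 25 × 30 µm rectangle with
12.5-µm hemispherical caps, scaled by 0.26 so the cell fits the default
256 × 256 × 12 grid at 0.065 µm/px and 0.2 µm z-step; geometric similarity
preserves the QC axis-ratio window and the area target scales as the square
of the footprint scale. The nucleus is an offset ellipsoid in the left
hemisphere. Granule radii are log-normal (median ≈ 0.72 µm, truncated to
0.40–0.90 µm, matching a size distribution peaked between 0.5 and 1.0 µm);
80% of granules are round (axis ratio ≤ 1.5) and the rest elongated up to
2.2. The granule marker is a tanh step of half-width 0.15 µm between cytosol
and a 10× interior. In depolymerized mode the tubulin channel is
`cytosol × exp(q(d))` with `q(d)` the quadratic interface landscape mapped
onto the signed Euclidean distance to the granule surface and anchored so the
bulk and peak levels realize the drawn `ln k_g` and `ln k_s` exactly
(realizability is a tested invariant). The landscape half-width default is
0.26 µm: comfortably inside the 0.39-µm measurement windows even with ±1 px
outline error, while keeping the imaged surface peak broader than the PSF as
observed in real data. True affinities are drawn from Gaussians with the
reported cohort means (−0.016 and 0.066 k_BT) and spreads (0.04 and
0.015 k_BT) of the order of the printed per-granule uncertainties; pairs
where the peak would not exceed both bulk levels are redrawn (<1% of draws).
Granule centres keep `R_i + R_j + 1.0` µm of separation so that no granule's
measurement windows overlap a neighbour's interface ring and the per-granule
ground truth stays well defined. In filament mode, straight segments
(microtubules are too rigid to bend at granule scale) are laid down with
midpoint density following the same Boltzmann weight.

Optics are a separable Gaussian PSF with σ_xy = 0.083 µm (the 195-nm
diffraction FWHM) and σ_z = 0.25 µm (a typical spinning-disc axial width),
followed by scaled-Poisson shot noise (default 1000 photons per intensity
unit); read noise is not modelled and there is no intensity calibration, so
the photon scale is a free parameter. Per-cell jitter covers orientation
(SD 1.2°, capped below the 3° QC limit), centre position (±0.3 µm), and
granule count (Poisson, mean 7; placement that saturates the packing drops
the remainder with a warning).

What the generator does *not* emulate: granule shape irregularity beyond
ellipsoids, spatial clustering of granules near the nucleus, chromatic
aberration, depth-dependent PSF, and fluorophore-environment effects on the
intensity–concentration proportionality. Passing recovery tests therefore
demonstrate the correctness of the measurement chain under the stated image
formation model, not robustness to every property of real acquisitions.

# Numerical choices and accuracy

Index order is R-native `[y, x, z]`, 1-based; all user-facing coordinates
and lengths are in µm. Rotation uses bilinear interpolation with mask
propagation (a pixel is masked if any contributing pixel is masked); 180°
flips are exact array reversals. 3D primitives that no installed package
provides (26-connectivity labelling, separable NA-aware box and Gaussian
filters, spherical dilation, the mask-propagating warp) are implemented in
C++. The `a0` search uses `optimize` on [10⁻⁴, 5] k_BT with tolerance
10⁻¹²; IRLS stops at 10⁻¹⁰ or 50 iterations, and a realization ending on the
search boundary counts as non-convergence (more than 1% aborts the fit).

One known systematic is worth stating plainly: the imaged interface peak is
a thin shell, and the lateral PSF removes about 0.010–0.015 k_BT from the
recovered cohort mean of `ln k_s` when truth is defined pre-optics (as it is
here). The recovered surface affinities on the default synthetic conditions
are therefore ≈0.052–0.054 k_BT against a rendered truth of 0.066 k_BT,
while the bulk affinity, whose windows sit in flat regions, is recovered
within its standard error. The same attenuation necessarily affects any
measurement made through these optics; it is reported, not corrected,
because the method defines the affinities operationally on the image.

Problem sizes used by the shipped experiments: the end-to-end recovery runs
40 cells of 256 × 256 × 12 voxels (~140 eligible granules); the fit-recovery
experiment uses n = 449 points and 1,000 realizations; oracle suites use 100
random models or 2 × 10⁴ samples.

# Limitations

- The quality-factor weighting and minimum are not uniquely determined by
  the method description; both are explicit configuration with defaults
  calibrated as described above.
- Surface distances are computed in the centroid plane (2D), matching the
  crop definition; a 3D variant is not implemented.
- Partition recovery is only asserted in the weak-partitioning regime
  (`k ≈ 1`), where intensity–concentration proportionality cancels.
- Real acquisitions are accepted through `read_acquisition()` (multi-page
  TIFF plus JSON sidecar); proprietary microscope formats are out of scope.
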