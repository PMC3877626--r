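---
title: "Region-based partial volume correction: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based partial volume correction: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical model behind the four corrections
implemented in `petgtm`, what the digital phantoms emulate, and the design
and numerical choices a maintainer would want to know. Everything empirical
stated here is computed by the package's test suite or by
`scripts/acceptance.R`; the vignette itself contains no numbers the code
does not reproduce.

## The transfer-matrix model and its assumptions

The model assumes the anatomy is segmented into N non-overlapping regions of
*constant* tracer uptake T_i, and that the scanner acts as a known linear
operator S on the underlying activity distribution. Writing m_i for region
i's tissue-fraction mask on the PET grid and RSF_i = S(m_i) for its regional
spread function, the measured image is I = Σ_i T_i RSF_i + noise. Sampling I
with any set of N functions w_j gives the square system W T = t with
W[j,i] = ∫ RSF_i w_j and t_j = ∫ I w_j, solved by dense LU factorization.

Two choices generate the four methods. The sampling functions are either the
sharp tissue-fraction masks (GTM, GTMo) or the RSFs themselves (sGTM,
sGTMo); the operator S is either convolution with a global 3D Gaussian PSF
(GTM, sGTM) or the full acquisition chain — forward projection, sinogram
blurring, filtered back-projection (GTMo, sGTMo). Symmetric sampling makes W
a Gram matrix; against stationary white noise the sGTM/sGTMo solve *is*
ordinary least squares on the source model, i.e. the minimum-variance linear
estimator — which is why its noise amplification and misregistration
sensitivity are lower, most visibly for structures below the PSF width.

The key assumptions are: segmentation correctness, uptake homogeneity per
region, and S matching the scanner. When the same S generates both the RSFs
and the image, the noiseless solve recovers T exactly (an algebraic
identity); the test suite asserts this to 1e-12 for all four methods. A
matrix-index note: the system is solved with rows indexed by sampling
region and columns by source region — the orientation under which the exact
identity holds for the non-symmetric methods.

On the literature's naming: "GTM" is the geometric transfer matrix method
with image-space RSFs; the trailing "o" (from sin*o*gram) marks the variants
whose RSFs are computed through the projection/reconstruction chain.

## The acquisition model

The projector is an idealized slice-parallel parallel-beam model: a 2D Radon
transform per transaxial slice (Joseph-style ray marching with bilinear
sampling at half-voxel steps), Gaussian blurring of the sinograms (radial
via the Fourier domain, axial by direct normalized convolution across
slices), and slice-wise 2D FBP. This replaces a cylindrical-scanner
geometry and 3D-reprojection FBP: it preserves everything the correction
mathematics needs — RSFs produced by project-blur-reconstruct, including
negative voxel values and streaks from the ramp filter — while remaining
exactly implementable. Negative RSF values are retained, never clipped;
their sum over a full partition must still be within 0.5% of unity at every
voxel, which the RSF constructor enforces.

Numerical choices that matter:

* **Backprojection as exact transpose.** The backprojector scatters the
  same bilinear weights the forward projector gathers, so
  ⟨Ax, y⟩ = ⟨x, Aᵀy⟩ to machine precision. FBP then computes
  `π · Aᵀ(filtered) / Aᵀ(1)`: the division by the cached sensitivity image
  (backprojection of an all-ones sinogram) removes the sub-percent
  deposit-density ripple of the discrete transpose, which otherwise peaks at
  the rotation center where the sampling lattices of all angles align.
* **Radial sampling at half the voxel pitch.** With radial bins at the
  voxel pitch the residual reconstruction error of a constant volume is
  ~0.4%; at half pitch it drops to ~0.14%, leaving comfortable margin under
  the 0.5% unity criterion. Defaults: 192 angles over [0, π), radial extent
  1.1 × the padded image diagonal, ramp × Hann at the Nyquist cutoff (also
  available: plain ramp, Shepp-Logan), held fixed between RSF computation
  and image simulation so both sides of the transfer equation see the same
  system.
* **Replicate-edge padding.** Images are padded transaxially by 10 voxels of
  replicated edge before projection and cropped after reconstruction. This
  mirrors the replicate-edge padding used for image-space convolution: both
  make the operator S preserve constants up to the FOV border, so mask
  partitions of unity survive S and the unity check is meaningful at edge
  voxels. The pad width is a numerical-accuracy parameter (it must cover the
  blur support plus the FBP's edge ringing), not a property of the phantoms.
* **FWHM ↔ sigma** uses σ = FWHM / (2√(2 ln 2)) throughout.

PSF calibration finds the radial and axial sinogram sigmas such that a
reconstructed point source has Gaussian-fitted FWHMs (three orthogonal
profiles, nonlinear least squares with a half-max interpolation fallback)
matching the targets — by default the measured scanner PSF of
7.23/7.14/6.65 mm. Because the in-plane blur is isotropic, the radial sigma
targets the mean of the x and y FWHMs; the two target values differ by 1.3%,
so both stay within the 2% calibration tolerance. The search is a
safeguarded secant iteration seeded by the quadrature approximation
target² ≈ intrinsic² + (2.355 σ)², which converges in a handful of
pipeline evaluations; targets below the discrete projector's intrinsic
resolution raise an error reporting the floor.

## The phantoms

**Sphere tank.** Six spheres with inner diameters 5, 10, 13, 17, 22 and
30 mm, all with 0.6 mm zero-uptake walls, at a 3:1 sphere-to-background
uptake ratio, on an isotropic 0.6 mm fine grid; the PET grid is 64 × 64 × 48
voxels of 2 × 2 × 3.15 mm. Spheres are placed two per axial level at three
levels so that each sphere's local background cylinder (20 mm beyond the
outer wall in every direction) stays clear of its neighbours' walls. The
digital tank fills the whole FOV: the transfer-matrix model requires
constant uptake per region, and an air ring inside the background VOI would
violate that; the physical tank-in-air geometry adds nothing to the
correction mathematics.

**Per-sphere 3×3 systems.** Each sphere is corrected with its own
three-region system (interior, wall, background), as one would analyze a
multi-sphere phantom. The three *source* regions are the interior, the wall
and the full background label; the *sampling* is local — the sharp VOIs
restricted to the background cylinder for GTM/GTMo, and for sGTM/sGTMo the
RSFs with all integrals restricted to the cylinder domain (which keeps W
symmetric). Restricting only the integration domain rather than truncating
the background source region matters: a cylinder-truncated background RSF
predicts spill deficits at the artificial cylinder boundary that the real
image does not have, which biases small-sphere uptakes by several percent,
and an unrestricted symmetric sampling lets the nearly collinear
interior/wall directions soak up model residuals from the other spheres.
With the local-domain construction all four methods recover the noiseless
truth per sphere to better than 0.7% (exactly, through the joint 13-region
system).

**Brain surrogate.** A procedural six-region head built from nested
ellipsoids — skin/muscle shell, grey-matter shell, white-matter core, and
merged left+right putamen and caudate pairs with volumes of the right order
(≈8 and ≈5 cm³) — on a 1.1 × 1.1 × 1.4 mm fine grid, with relative uptakes
4.5 (putamen), 4.0 (caudate), 1.0 (skin/muscle), 2.5 (grey), 2.0 (white), 0
(background), the profile of striatal dopaminergic tracer imaging. The
five uptakes follow the convention that lists putamen and caudate once
each, so left and right structures are merged into single VOIs; a
user-supplied atlas with per-side labels works equally. This surrogate is
synthetic: it reproduces the size/contrast structure that drives
partial-volume behaviour, not individual anatomy, so passing tests support
the method's behaviour by region scale, not anatomical claims.

**Downsampling.** VOI masks and the ideal activity map are interpolated to
the PET grid with plain trilinear interpolation at PET voxel centers —
self-consistent because downsampling is linear, so the ideal PET-grid image
equals Σ T_i m_i exactly whatever the interpolant. An optional box-average
prefilter (`antialias = TRUE`) makes the fractions volume-accurate, but
smears 0.6 mm walls and sub-voxel interiors into nearly collinear masks:
for the 5 mm sphere it raises the interior/wall Gram condition number about
3-fold and the per-realization RC spread about 4-fold. Plain trilinear is
therefore the default for all experiments.

**Noise.** Stationary, uncorrelated Gaussian noise added after
reconstruction, standard deviation 25% of the reference mean — the
background (tank) uptake for the spheres; for the brain, whose background
is zero, the mean ideal uptake over the head voxels. One noise field is
drawn per realization and shared by the image-space and sinogram-space
simulations, so method comparisons are paired. A master seed draws one
sub-seed per realization; experiments are bitwise reproducible. What this
noise model does *not* emulate: projection-domain Poisson statistics and
the spatial correlation a reconstruction would imprint on them, attenuation,
scatter, randoms, or detector effects — so the Monte-Carlo results speak to
noise *propagation* through the corrections, not to absolute clinical noise
levels.

## The evaluation harness

`run_accuracy_experiment()` reports, per (system, method, region), the mean
and standard deviation across realizations of the recovery coefficient
RC = corrected/true, the noise magnification factor NMF = CV(T)/CV(t) — each
method's corrected values against *its own* raw samples, mask-weighted for
GTM/GTMo and RSF-weighted for sGTM/sGTMo — and the absolute corrected
uptake. RC is undefined for zero-uptake regions (sphere walls, brain
background); those are reported as absolute residuals and excluded from RC
summaries.

`run_misregistration_experiment()` shifts the fine-grid labels by whole fine
voxels (masks are categorical; at 0.6 mm granularity the rounding error is
far below the 1–10 mm shifts studied), re-downsamples, recomputes RSFs and
the whole correction against the fixed PET image, and reports RC normalized
to its zero-shift value, one axis at a time. With `recompute_rsfs = FALSE`
the harness instead displaces the PET image by the opposite offset — the
same relative misregistration — so every CT-derived object is bitwise
fixed: this realizes, and the tests assert, that registration errors leave
the weighting matrix untouched and enter only through the sampled values.

Problem sizes: the full-fidelity setting is 100 realizations on the
64 × 64 × 48 grid; the packaged experiments and the acceptance script use 50
realizations, which resolves mean RCs to a fraction of a percent for all
regions of 10 mm and larger. A deliberate caveat, recorded here rather than
hidden: for the 5 mm sphere (2.5 PET voxels across, with a 0.6 mm cold wall,
under a 7.2 mm PSF) the per-realization RC spread is ~0.5 even for the
minimum-variance symmetric estimator and several times that for GTM/GTMo,
so the mean RC of the smallest sphere is Monte-Carlo-limited at any
realistic realization count; its deviation from 1 in the experiment reports
reflects that variance, not a correctable bias — the noiseless solve is
exact. Sub-resolution objects with cold shells are simply at the edge of
what any blind 3-region linear correction can estimate from one image.

## Known limitations

* The projector is slice-parallel; oblique lines of response and true 3D
  reprojection FBP are out of scope, as are attenuation, scatter and
  detector-gap effects of physical scanners.
* The PSF is treated as shift-invariant within each method family.
* Regularization beyond an optional ridge term is not provided; severely
  ill-conditioned systems (condition number above 1e6) trigger a warning
  and are better handled by merging regions.
* NIfTI-1 is the native volume format; a minimal interfile reader is
  provided for interoperability. Sinograms are runtime objects.
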