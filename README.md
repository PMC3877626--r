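# petgtm

Region-based partial volume correction (PVC) for PET, in image space and in
sinogram space.

PET images are blurred by the scanner's point-spread function (PSF) and
sampled on voxels much coarser than anatomical (CT/MR) images. Both effects
bias regional uptake measurements: small hot structures lose counts to their
surroundings (spillover) and voxels straddling tissue boundaries mix several
tissues (the tissue fraction effect). `petgtm` implements the geometric
transfer matrix family of corrections for users who quantify regional tracer
uptake — small-structure oncology phantom studies, striatal neuroimaging —
and for methodologists who want a fully simulatable testbed for these
corrections.

## The model

Anatomical images are segmented into N non-overlapping volumes of interest
(VOIs) with assumed-constant uptake T_i. Each VOI's binary mask is
interpolated to the PET grid (tissue fractions) and pushed through the
scanner's resolution model to give its *regional spread function* (RSF) —
the image a unit-uptake region would produce. Measured regional samples obey
the linear system

    W T = t,    W[j, i] = ∫ RSF_i(r) · w_j(r) dr,    t_j = ∫ I(r) · w_j(r) dr

where I is the measured PET image and w_j the sampling function of region j.
Four methods arise from two independent choices:

| | RSFs by 3D PSF convolution | RSFs by project–blur–reconstruct |
|---|---|---|
| **sample with sharp VOI masks** | GTM | GTMo |
| **sample with the RSFs themselves** | sGTM | sGTMo |

Sampling with the RSFs makes W a symmetric Gram matrix, which damps noise
amplification and misregistration sensitivity; computing RSFs in sinogram
space (forward projection, Gaussian blurring of the sinograms, filtered
back-projection) reproduces reconstruction-induced structure — including
negative lobes and streaks — that a global image-space PSF cannot.

The corrected uptakes are `T = W⁻¹ t` (dense LU solve). Residual resolution
effects cancel exactly when the same system model generates both the RSFs
and the image — the package's central invariant, tested to 1e-12.

The package also provides:

* an idealized slice-parallel parallel-beam projector (Joseph-style ray
  marching) whose backprojector is its exact matrix transpose, with
  quantitative FBP (Ram-Lak × Hann/Shepp-Logan/ramp apodization),
* PSF calibration: sinogram-domain Gaussian sigmas fitted so a reconstructed
  point source matches target FWHMs (e.g. the measured 7.23/7.14/6.65 mm),
* digital phantoms: a six-sphere tank (5–30 mm inner diameters, 0.6 mm cold
  walls, 3:1 sphere-to-background ratio) and a six-region brain surrogate
  (putamen 4.5, caudate 4.0, skin/muscle 1.0, grey 2.5, white 2.0,
  background 0), with tissue-fraction downsampling and stationary Gaussian
  noise (25% of the reference mean by default),
* a Monte-Carlo harness for recovery coefficients (RC = measured/true),
  noise magnification factors (NMF = CV after / CV before correction), and
  misregistration sweeps, returning tidy tibbles with `autoplot()` methods.

## Worked example

```r
library(petgtm)

# a small two-sphere phantom on a 32 x 32 x 12 PET grid
spec <- sphere_phantom_spec(
  spheres = data.frame(name = c("sphereA", "sphereB"),
                       cx = c(-11, 11), cy = c(-4, 6), cz = c(0, 0),
                       inner_diameter = c(13, 8), wall = 0.6),
  pet_shape = c(32L, 32L, 12L), pet_voxel = c(2, 2, 3))
ph   <- make_sphere_phantom(spec)
grid <- grid_spec(c(32L, 32L, 12L), c(2, 2, 3))
geom <- projection_geometry(grid, n_angles = 96L, edge_pad = 8L)
blur <- calibrate_blur(c(7.23, 7.14, 6.65), geom)

ideal <- downsample_to_pet(ph$activity, grid)
pet   <- add_noise(simulate_acquisition(ideal, blur, geom),
                   noise_fraction = 0.25, reference_mean = 1, rng_seed = 7)

fit <- apply_pvc(pet, ph$labels, method = "sGTMo", blur = blur, geometry = geom)
tidy(fit)
```

```
# A tibble: 5 × 4
  region        sampled corrected self_weight
  <chr>           <dbl>     <dbl>       <dbl>
1 background    147261.    1.00     144361.
2 sphereA_inner   1822.    3.06        375.
3 sphereA_wall     503.   -0.0541       22.7
4 sphereB_inner    322.    3.21         35.3
5 sphereB_wall     153.    0.0871        6.50
```

`sampled` is the RSF-weighted image sample t_j (here in mm³·activity units);
`corrected` is the solved regional uptake T_j. The uncorrected 8 mm sphere
reads only 51% of its true uptake in this image; the correction restores
both spheres to near their true value 3 (3.06 and 3.21 at this noise level),
and the cold walls scatter around 0 since they are far below the 7 mm
resolution.

The Monte-Carlo harness summarizes accuracy and precision per method:

```r
res <- run_accuracy_experiment(ph, methods = c("GTMo", "sGTMo"),
                               n_realizations = 50, seed = 1,
                               psf_fwhm = c(7.23, 7.14, 6.65),
                               blur = blur, geometry = geom)
autoplot(res)
```

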