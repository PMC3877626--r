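# Small fixtures shared across the unit tests, plus a memoized full-scale
# fixture for the acceptance suite. Everything is generated in code.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# --- small fixtures -------------------------------------------------------

tiny_pet_grid <- function() grid_spec(c(32L, 32L, 12L), c(2, 2, 3))

# two spheres (13 and 8 mm) on a 64 x 64 x 36 mm FOV, 0.6 mm fine grid
tiny_sphere_spec <- function() {
  sphere_phantom_spec(
    spheres = data.frame(name = c("sphereA", "sphereB"),
                         cx = c(-11, 11), cy = c(-4, 6), cz = c(0, 0),
                         inner_diameter = c(13, 8), wall = 0.6),
    pet_shape = c(32L, 32L, 12L), pet_voxel = c(2, 2, 3),
    n_realizations = 10L)
}

tiny_sphere_phantom <- function() memo("tiny_sphere", make_sphere_phantom(tiny_sphere_spec()))

tiny_geometry <- function(n_angles = 96L)
  memo(paste0("tiny_geom", n_angles),
       projection_geometry(tiny_pet_grid(), n_angles = n_angles, edge_pad = 8L))

tiny_blur <- function() blur_model(2.6, 2.4)

tiny_masks <- function() {
  memo("tiny_masks", pet_masks(tiny_sphere_phantom()$labels, tiny_pet_grid()))
}

tiny_model <- function() {
  memo("tiny_model",
       precompute_model(tiny_sphere_phantom(), psf_fwhm = c(7.23, 7.14, 6.65),
                        blur = tiny_blur(), geometry = tiny_geometry(),
                        per_sphere = FALSE))
}

# supersampled 2D disk mask (fraction-accurate pixelization)
disk_image <- function(n = 48, vs = 2, radius = 20, oversample = 8, nz = 1) {
  f <- oversample
  xs <- (-(n * f) / 2 + seq_len(n * f) - 0.5) * (vs / f)
  fine <- (outer(xs^2, xs^2, "+") <= radius^2) + 0
  disk <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    disk[i, j] <- mean(fine[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  activity_volume(array(disk, c(n, n, nz)), c(vs, vs, 3))
}

# --- full-scale fixtures for the acceptance suite -------------------------

study_geometry <- function() {
  memo("study_geom",
       projection_geometry(grid_spec(c(64L, 64L, 48L), c(2, 2, 3.15)),
                           n_angles = 192L, edge_pad = 10L))
}

study_blur <- function() {
  memo("study_blur", calibrate_blur(c(7.23, 7.14, 6.65), study_geometry()))
}

study_sphere_model <- function() {
  memo("study_sphere_model", {
    ph <- make_sphere_phantom()
    list(phantom = ph,
         model = precompute_model(ph, psf_fwhm = c(7.23, 7.14, 6.65),
                                  blur = study_blur(), geometry = study_geometry(),
                                  per_sphere = TRUE))
  })
}

study_brain_model <- function() {
  memo("study_brain_model", {
    bp <- make_brain_phantom()
    list(phantom = bp,
         model = precompute_model(bp, psf_fwhm = c(7.23, 7.14, 6.65),
                                  blur = study_blur(), geometry = study_geometry(),
                                  per_sphere = FALSE))
  })
}

study_sphere_experiment <- function() {
  memo("study_sphere_experiment", {
    sm <- study_sphere_model()
    run_accuracy_experiment(sm$phantom, model = sm$model,
                            n_realizations = 50L, seed = 1L)
  })
}
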