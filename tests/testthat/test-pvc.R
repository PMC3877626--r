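test_that("image-space RSFs preserve partitions and match dense convolution", {
  pg <- tiny_pet_grid()
  ones <- activity_volume(array(1, pg$shape), pg$voxel_size, pg$origin)
  rs <- compute_rsf_image_space(list(all = ones), c(7.23, 7.14, 6.65))
  expect_equal(max(abs(rs$rsfs$all$values - 1)), 0, tolerance = 1e-12)
  # complementary half-spaces: monotone sigmoids summing to one
  left <- array(0, pg$shape); left[1:16, , ] <- 1
  masks <- list(l = activity_volume(left, pg$voxel_size, pg$origin),
                r = activity_volume(1 - left, pg$voxel_size, pg$origin))
  rs2 <- compute_rsf_image_space(masks, c(7, 7, 7))
  total <- rs2$rsfs$l$values + rs2$rsfs$r$values
  expect_lt(max(abs(total - 1)), 1e-6)
  prof <- rs2$rsfs$l$values[, 16, 6]
  expect_true(all(diff(prof) <= 1e-12))
  expect_true(all(rs2$rsfs$l$values >= -1e-12 & rs2$rsfs$l$values <= 1 + 1e-12))
  # center value of a sphere RSF against a brute-force dense spatial convolution
  masks_t <- tiny_masks()
  rsfs <- compute_rsf_image_space(masks_t, c(7, 7, 7))
  m <- masks_t$sphereA_inner
  ctr <- arrayInd(which.max(m$values), dim(m$values))
  sig <- fwhm_to_sigma(c(7, 7, 7)) / m$voxel_size
  d <- dim(m$values)
  kx <- exp(-((seq_len(d[1]) - ctr[1])^2) / (2 * sig[1]^2))
  ky <- exp(-((seq_len(d[2]) - ctr[2])^2) / (2 * sig[2]^2))
  kz <- exp(-((seq_len(d[3]) - ctr[3])^2) / (2 * sig[3]^2))
  w <- outer(outer(kx, ky), kz); w <- w / sum(w)
  expect_equal(rsfs$rsfs$sphereA_inner$values[ctr[1], ctr[2], ctr[3]],
               sum(w * m$values), tolerance = 1e-3)
  # non-partition masks are rejected
  expect_error(compute_rsf_image_space(list(half = masks$l), c(7, 7, 7)),
               "partition of unity")
})

test_that("sinogram-space RSFs satisfy unity, linearity and expected negativity", {
  geom <- tiny_geometry()
  blur <- tiny_blur()
  pg <- tiny_pet_grid()
  ones <- activity_volume(array(1, pg$shape), pg$voxel_size, pg$origin)
  rs1 <- compute_rsf_sinogram_space(list(all = ones), blur, geom)
  expect_lt(max(abs(rs1$rsfs$all$values - 1)), 0.005)
  # complement masks reproduce the all-ones acquisition by linearity
  left <- array(0, pg$shape); left[1:16, , ] <- 1
  masks <- list(l = activity_volume(left, pg$voxel_size, pg$origin),
                r = activity_volume(1 - left, pg$voxel_size, pg$origin))
  rs2 <- compute_rsf_sinogram_space(masks, blur, geom)
  lin <- rs2$rsfs$l$values + rs2$rsfs$r$values
  expect_lt(max(abs(lin - rs1$rsfs$all$values)), 1e-9)
  # a small sphere's reconstructed RSF contains negative values (not clipped)
  model <- tiny_model()
  expect_lt(min(model$rsf_os$rsfs$sphereB_inner$values), 0)
  # deviation beyond tolerance is an error with the max reported
  expect_error(compute_rsf_sinogram_space(list(half = masks$l), blur, geom),
               "deviate from unity")
})

test_that("GTM systems satisfy the algebraic identity and the 3:1 sphere ratio", {
  pg <- tiny_pet_grid()
  # N = 1 full-FOV region with constant image recovers the constant exactly
  ones <- activity_volume(array(1, pg$shape), pg$voxel_size, pg$origin)
  img_c <- activity_volume(array(2.7, pg$shape), pg$voxel_size, pg$origin)
  rs1 <- compute_rsf_image_space(list(all = ones), c(7, 7, 7))
  fit1 <- solve_pvc(build_system_gtm(rs1, list(all = ones), img_c))
  expect_equal(unname(fit1$T), 2.7, tolerance = 1e-12)
  # matched image: exact recovery through the full joint system
  model <- tiny_model()
  truth <- phantom_uptakes(tiny_sphere_phantom()$spec)[names(model$masks)]
  for (fam in c("is", "os")) {
    rs <- if (fam == "is") model$rsf_is else model$rsf_os
    img <- if (fam == "is") model$img_is else model$img_os
    fit <- solve_pvc(build_system_gtm(rs, model$masks, img), condition_warn = Inf)
    expect_equal(unname(fit$T), unname(truth), tolerance = 1e-8)
    # recovered sphere-to-background ratio = 3 within 1e-3
    expect_equal(fit$T[["sphereA_inner"]] / fit$T[["background"]], 3,
                 tolerance = 1e-3)
  }
  # omega column sums equal mask volumes (normalized PSF conserves integrals)
  sys <- build_system_gtm(model$rsf_is, model$masks, model$img_is)
  vols <- vapply(model$masks, function(m) sum(m$values) * voxel_volume(m), numeric(1))
  expect_equal(unname(colSums(sys$omega)), unname(vols), tolerance = 1e-3)
  # grid mismatch errors
  off <- activity_volume(array(1, c(8, 8, 4)), c(2, 2, 3))
  expect_error(build_system_gtm(rs1, list(all = ones), off), "grid mismatch")
})

test_that("symmetric systems are symmetric, PSD, and exactly invert matched images", {
  model <- tiny_model()
  sys <- build_system_sgtm(model$rsf_is, model$img_is)
  expect_lt(max(abs(sys$omega - t(sys$omega))) / max(abs(sys$omega)), 1e-10)
  ev <- eigen(sys$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(ev)))   # Gram matrix of image-space RSFs
  truth <- phantom_uptakes(tiny_sphere_phantom()$spec)[model$rsf_is$region_names]
  for (fam in c("is", "os")) {
    rs <- if (fam == "is") model$rsf_is else model$rsf_os
    img <- if (fam == "is") model$img_is else model$img_os
    fit <- solve_pvc(build_system_sgtm(rs, img), condition_warn = Inf)
    expect_equal(unname(fit$T), unname(truth), tolerance = 1e-8)
  }
})

test_that("the linear solve is exact, diagnosable and guards singularity", {
  id <- transfer_system(diag(3), c(1, 2, 3), "GTM", letters[1:3])
  expect_equal(solve_pvc(id)$T, c(a = 1, b = 2, c = 3))
  two <- transfer_system(matrix(c(2, 1, 1, 2), 2), c(4, 5), "sGTM", c("x", "y"))
  expect_equal(solve_pvc(two)$T, c(x = 1, y = 2), tolerance = 1e-12)
  set.seed(3)
  A <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  tv <- rnorm(6)
  fit <- solve_pvc(transfer_system(A, tv, "GTM", paste0("r", 1:6)))
  expect_lt(max(abs(A %*% fit$T - tv)) / max(abs(tv)), 1e-10)
  sing <- transfer_system(matrix(c(1, 1, 1, 1), 2), c(1, 1), "GTM", c("p", "q"))
  expect_error(suppressWarnings(solve_pvc(sing)), "merging regions")
  illcond <- transfer_system(matrix(c(1, 0, 0, 1e-9), 2), c(1, 1), "GTM", c("p", "q"))
  expect_warning(solve_pvc(illcond), "condition number")
  # ridge regularization perturbs the solve
  expect_lt(solve_pvc(illcond, condition_warn = Inf, ridge = 1)$T[["q"]], 1)
})

test_that("apply_pvc orchestrates all four methods with shared RSF sets", {
  model <- tiny_model()
  ph <- tiny_sphere_phantom()
  truth <- phantom_uptakes(ph$spec)
  fits_is <- apply_pvc(model$img_is, ph$labels, method = c("GTM", "sGTM"),
                       psf_fwhm = c(7.23, 7.14, 6.65))
  expect_length(attr(fits_is, "rsf_sets"), 1L)  # computed once, shared
  fits_os <- apply_pvc(model$img_os, ph$labels, method = c("GTMo", "sGTMo"),
                       blur = tiny_blur(), geometry = tiny_geometry())
  for (f in c(fits_is, fits_os)) {
    tr <- truth[f$region_names]
    expect_lt(max(abs(f$T[tr > 0] / tr[tr > 0] - 1)), 0.005)
    expect_lt(max(abs(f$T[tr == 0])), 0.005)
  }
  # scale equivariance: scaling the image scales the corrected uptakes
  img2 <- activity_volume(model$img_is$values * 3.5, model$img_is$voxel_size,
                          model$img_is$origin)
  f2 <- apply_pvc(img2, ph$labels, method = "GTM", psf_fwhm = c(7.23, 7.14, 6.65))
  expect_equal(f2$T, fits_is$GTM$T * 3.5, tolerance = 1e-10)
  # missing configuration errors
  expect_error(apply_pvc(model$img_is, ph$labels, method = "GTM"), "psf_fwhm")
  expect_error(apply_pvc(model$img_os, ph$labels, method = "sGTMo"), "blur model")
})

test_that("solved systems tidy into per-region tibbles", {
  fit <- solve_pvc(transfer_system(matrix(c(2, 1, 1, 2), 2), c(4, 5),
                                   "sGTM", c("x", "y")))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("region", "sampled", "corrected", "self_weight"))
  expect_equal(td$corrected, c(1, 2), tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$method, "sGTM")
  expect_lt(gl$max_residual, 1e-12)
})
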