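test_that("sphere phantom geometry matches brute-force voxel enumeration", {
  # one 10 mm sphere on a 0.5 mm grid; count inner voxels independently
  spec <- sphere_phantom_spec(
    spheres = data.frame(name = "s10", cx = 1.3, cy = -0.7, cz = 0.4,
                         inner_diameter = 10, wall = 0.6),
    fine_voxel = c(0.5, 0.5, 0.5), pet_shape = c(16L, 16L, 12L),
    pet_voxel = c(2, 2, 3))
  ph <- make_sphere_phantom(spec)
  lab <- ph$labels
  # brute force: loop over all voxel centers
  d <- dim(lab$labels)
  ctr <- lapply(1:3, function(ax) lab$origin[ax] + (seq_len(d[ax]) - 0.5) * 0.5)
  n_inner <- 0L; n_wall <- 0L
  for (k in seq_len(d[3])) {
    dz2 <- (ctr[[3]][k] - 0.4)^2
    r2 <- outer((ctr[[1]] - 1.3)^2, (ctr[[2]] + 0.7)^2, "+") + dz2
    n_inner <- n_inner + sum(r2 <= 5^2)
    n_wall <- n_wall + sum(r2 <= 5.6^2 & r2 > 5^2)
  }
  expect_identical(sum(lab$labels == 1L), n_inner)
  expect_identical(sum(lab$labels == 2L), n_wall)
})

test_that("default sphere phantom has 13 labels and exact uptake assignment", {
  ph <- tiny_sphere_phantom()  # 2 spheres -> 5 labels; same construction
  expect_length(ph$labels$label_names, 5L)
  expect_length(default_spheres()$name, 6L)  # 6 spheres -> 13 labels
  # ideal activity is exactly sum of uptake x mask on the fine grid
  upt <- phantom_uptakes(ph$spec)
  recon <- array(upt[ph$labels$labels + 1L], dim(ph$labels$labels))
  expect_identical(ph$activity$values, recon)
})

test_that("degenerate and invalid sphere definitions are handled", {
  spec0 <- sphere_phantom_spec(
    spheres = data.frame(name = "null", cx = 0, cy = 0, cz = 0,
                         inner_diameter = 0, wall = 0),
    pet_shape = c(16L, 16L, 8L), pet_voxel = c(2, 2, 3))
  ph <- make_sphere_phantom(spec0)
  expect_true(all(ph$labels$labels == 0L))
  expect_true(all(ph$activity$values == ph$spec$uptake[["background"]]))

  overlap <- sphere_phantom_spec(
    spheres = data.frame(name = c("a", "b"), cx = c(0, 5), cy = 0, cz = 0,
                         inner_diameter = c(10, 10), wall = 0.6),
    pet_shape = c(32L, 32L, 8L), pet_voxel = c(2, 2, 3))
  expect_error(make_sphere_phantom(overlap), "a and b")

  outside <- sphere_phantom_spec(
    spheres = data.frame(name = "far", cx = 40, cy = 0, cz = 0,
                         inner_diameter = 10, wall = 0.6),
    pet_shape = c(16L, 16L, 8L), pet_voxel = c(2, 2, 3))
  expect_error(make_sphere_phantom(outside), "exceeds the grid")
})

test_that("tissue-fraction masks partition unity after downsampling", {
  masks <- tiny_masks()
  total <- Reduce(`+`, lapply(masks, function(m) m$values))
  expect_lt(max(abs(total - 1)), 1e-6)
  # fractions stay within [0, 1]
  for (m in masks) expect_true(all(m$values >= -1e-12 & m$values <= 1 + 1e-12))
})

test_that("downsampling preserves constants and fractionalizes boundaries", {
  fine <- activity_volume(array(1, c(40, 40, 20)), c(0.6, 0.6, 0.6))
  pg <- grid_spec(c(10L, 10L, 4L), c(2, 2, 3),
                  origin = c(-10, -10, -6) + c(2, 2, 0) / 2)
  for (aa in c(TRUE, FALSE)) {
    down <- downsample_to_pet(fine, pg, antialias = aa)
    expect_equal(max(abs(down$values - 1)), 0, tolerance = 1e-12)
  }
  # binary half-space: boundary voxels fractional, interior 1, exterior 0
  hs <- array(0, c(60, 20, 20)); hs[1:31, , ] <- 1  # plane at x = 0.6 mm offset
  hsv <- activity_volume(hs, c(0.6, 0.6, 0.6))
  down <- downsample_to_pet(hsv, grid_spec(c(18L, 6L, 4L), c(2, 2, 3)),
                            antialias = TRUE)
  mid <- down$values[, 3, 2]
  expect_true(all(mid[1:7] == 1))
  expect_true(all(mid[12:18] == 0))
  expect_true(any(mid > 0 & mid < 1))
})

test_that("antialiased sphere fractions agree with a supersampled volume-fraction oracle", {
  spec <- tiny_sphere_spec()
  ph <- make_sphere_phantom(spec)
  pg <- tiny_pet_grid()
  frac <- downsample_to_pet(label_masks(ph$labels)[["sphereA_inner"]], pg,
                            antialias = TRUE)
  # oracle: 8x supersampled volume fraction of the analytic sphere per PET voxel
  oracle_fraction <- function(i, j, k) {
    f <- 8
    xs <- pg$origin[1] + (i - 1) * 2 + (seq_len(f) - 0.5) * 2 / f
    ys <- pg$origin[2] + (j - 1) * 2 + (seq_len(f) - 0.5) * 2 / f
    zs <- pg$origin[3] + (k - 1) * 3 + (seq_len(f) - 0.5) * 3 / f
    d2 <- outer(outer((xs + 11)^2, (ys + 4)^2, "+"), zs^2, "+")
    mean(d2 <= 6.5^2)
  }
  # five boundary voxels (fraction strictly inside (0,1))
  idx <- which(frac$values > 0.2 & frac$values < 0.8, arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), length.out = 5), , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    expect_equal(frac$values[idx[r, 1], idx[r, 2], idx[r, 3]],
                 oracle_fraction(idx[r, 1], idx[r, 2], idx[r, 3]),
                 tolerance = 0.35)  # box+trilinear vs exact volume fraction
  }
})

test_that("added noise has the prescribed level, determinism and independence", {
  img <- activity_volume(array(2, c(50, 50, 50)), c(1, 1, 1))
  expect_identical(add_noise(img, 0, 1, 1L)$values, img$values)
  noisy <- add_noise(img, 0.25, 1, 42L)
  expect_equal(stats::sd(noisy$values - img$values), 0.25, tolerance = 0.01)
  expect_equal(add_noise(img, 0.25, 1, 42L)$values, noisy$values)
  other <- add_noise(img, 0.25, 1, 43L)
  expect_false(identical(other$values, noisy$values))
  rho <- stats::cor(as.numeric(noisy$values - img$values),
                    as.numeric(other$values - img$values))
  expect_lt(abs(rho), 0.01)
})

test_that("label shifting is exact on the fine grid and round-trips", {
  ph <- tiny_sphere_phantom()
  lab <- ph$labels
  expect_identical(shift_labels(lab, c(0, 0, 0))$labels, lab$labels)
  one <- shift_labels(lab, c(lab$voxel_size[1], 0, 0))
  expect_identical(one$labels[2:dim(lab$labels)[1], , ],
                   lab$labels[1:(dim(lab$labels)[1] - 1), , ])
  # +10 then -10 mm restores the interior
  rt <- shift_labels(shift_labels(lab, c(10, 0, 0)), c(-10, 0, 0))
  n <- round(10 / lab$voxel_size[1])
  d <- dim(lab$labels)
  expect_identical(rt$labels[(n + 1):(d[1] - n), , ],
                   lab$labels[(n + 1):(d[1] - n), , ])
  expect_warning(shift_labels(lab, c(12, 0, 0)), "10 mm")
})

test_that("brain phantom assigns uptakes exactly and validates the uptake map", {
  atlas <- surrogate_brain_atlas(shape = c(60L, 60L, 50L))
  spec <- brain_phantom_spec(pet_shape = c(24L, 24L, 16L))
  bp <- make_brain_phantom(spec, atlas)
  # per-region voxel means equal the assigned uptakes exactly
  for (id in seq_along(atlas$label_names) - 1L) {
    sel <- atlas$labels == id
    if (!any(sel)) next
    expect_equal(unique(as.numeric(bp$activity$values[sel])),
                 unname(spec$uptake[[atlas$label_names[id + 1L]]]))
  }
  # voxel counts match an independent label histogram
  hist <- tabulate(atlas$labels + 1L, nbins = 6L)
  for (id in 0:5)
    expect_identical(sum(atlas$labels == id), hist[id + 1L])
  # all-zero uptake map -> all-zero activity
  zspec <- brain_phantom_spec(uptake = stats::setNames(rep(0, 6), atlas$label_names))
  expect_true(all(make_brain_phantom(zspec, atlas)$activity$values == 0))
  # missing label is reported by name
  bad <- brain_phantom_spec(uptake = c(background = 0, putamen = 4.5, caudate = 4,
                                       skin_muscle = 1, grey_matter = 2.5))
  expect_error(make_brain_phantom(bad, atlas), "white_matter")
})

test_that("noise realizations from distinct master-seed streams are reproducible", {
  expect_identical(realization_seeds(7L, 10L), realization_seeds(7L, 10L))
  expect_false(any(duplicated(realization_seeds(7L, 100L))))
})
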