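#' Sphere phantom specification
#'
#' Describes the digital hot-sphere tank phantom: six fillable spheres with
#' inner diameters spanning 5--30 mm and 0.6 mm cold walls, in a warm
#' background, with a sphere-to-background uptake ratio of 3:1. The fine
#' (CT-like) grid uses isotropic 0.6 mm voxels; the PET grid defaults to
#' 64 x 64 x 48 voxels of 2 x 2 x 3.15 mm.
#'
#' Spheres are placed two per axial level at three levels so that every
#' sphere's local background cylinder (20 mm margin beyond the outer wall)
#' stays clear of neighbouring sphere walls. The digital tank fills the
#' reconstructed FOV: every voxel outside a sphere carries background uptake,
#' which keeps each VOI's uptake constant as the transfer-matrix model
#' assumes.
#'
#' @param spheres data frame with columns `name`, `cx`, `cy`, `cz` (center,
#'   mm), `inner_diameter` (mm), `wall` (mm). Defaults to the six-sphere
#'   layout.
#' @param fine_voxel fine grid spacing, mm (isotropic 0.6 by default).
#' @param pet_shape,pet_voxel PET grid voxel counts and spacing.
#' @param uptake named uptakes: inner, wall, background.
#' @param noise_fraction Gaussian noise std relative to the reference mean.
#' @param n_realizations Monte-Carlo realization count.
#' @param background_margin mm margin of the per-sphere background cylinder
#'   beyond the outer wall (at least 20 mm).
#' @return a `sphere_phantom_spec` list.
#' @export
sphere_phantom_spec <- function(spheres = default_spheres(),
                                fine_voxel = c(0.6, 0.6, 0.6),
                                pet_shape = c(64L, 64L, 48L),
                                pet_voxel = c(2, 2, 3.15),
                                uptake = c(inner = 3, wall = 0, background = 1),
                                noise_fraction = 0.25,
                                n_realizations = 100L,
                                background_margin = 20) {
  stopifnot(all(c("name", "cx", "cy", "cz", "inner_diameter", "wall") %in% names(spheres)),
            all(spheres$inner_diameter >= 0), all(spheres$wall >= 0),
            all(uptake >= 0), noise_fraction >= 0, n_realizations >= 1,
            background_margin >= 20)
  fine_voxel <- check_spacing(fine_voxel)
  pet_voxel <- check_spacing(pet_voxel)
  if (any(pet_voxel < fine_voxel)) stop("PET voxel size must be >= fine voxel size")
  if (anyDuplicated(spheres$name)) stop("sphere names must be unique")
  structure(list(spheres = spheres, fine_voxel = fine_voxel,
                 pet_shape = as.integer(pet_shape), pet_voxel = pet_voxel,
                 uptake = uptake, noise_fraction = noise_fraction,
                 n_realizations = as.integer(n_realizations),
                 background_margin = background_margin),
            class = "sphere_phantom_spec")
}

#' @rdname sphere_phantom_spec
#' @export
default_spheres <- function() {
  data.frame(
    name = c("sphere30", "sphere05", "sphere22", "sphere10", "sphere17", "sphere13"),
    cx   = c(-24.4, 24.4,     0,      0,     0,     0),
    cy   = c(0,     0,    -24.4,  24.4, -24.4,  24.4),
    cz   = c(0,     0,     50.4,  50.4, -50.4, -50.4),
    inner_diameter = c(30, 5, 22, 10, 17, 13),
    wall = 0.6
  )
}

#' Generate the digital sphere phantom
#'
#' Builds the fine-grid label volume (per sphere: inner and wall labels, plus
#' one shared background label 0) and the ideal fine-grid activity volume
#' with inner uptake 3, wall uptake 0 and background uptake 1 (relative
#' units). Geometry is analytic: a voxel is labeled by the distance from its
#' center to each sphere center.
#'
#' @param spec a `sphere_phantom_spec`.
#' @return list with elements `labels` (`label_volume`), `activity`
#'   (`activity_volume`) and `spec`.
#' @export
make_sphere_phantom <- function(spec = sphere_phantom_spec()) {
  stopifnot(inherits(spec, "sphere_phantom_spec"))
  fov <- spec$pet_shape * spec$pet_voxel
  fine_shape <- ceiling(fov / spec$fine_voxel)
  origin <- -fine_shape * spec$fine_voxel / 2
  sp <- spec$spheres
  r_out <- sp$inner_diameter / 2 + sp$wall
  # pre-flight geometry checks
  half_fov <- fine_shape * spec$fine_voxel / 2
  for (s in seq_len(nrow(sp))) {
    ctr <- c(sp$cx[s], sp$cy[s], sp$cz[s])
    if (any(abs(ctr) + r_out[s] > half_fov))
      stop("sphere ", sp$name[s], " exceeds the grid")
  }
  if (nrow(sp) > 1) {
    for (a in seq_len(nrow(sp) - 1)) for (b in seq((a + 1), nrow(sp))) {
      d <- sqrt((sp$cx[a] - sp$cx[b])^2 + (sp$cy[a] - sp$cy[b])^2 + (sp$cz[a] - sp$cz[b])^2)
      if (d < r_out[a] + r_out[b])
        stop("spheres overlap: ", sp$name[a], " and ", sp$name[b])
    }
  }
  cx <- origin[1] + (seq_len(fine_shape[1]) - 0.5) * spec$fine_voxel[1]
  cy <- origin[2] + (seq_len(fine_shape[2]) - 0.5) * spec$fine_voxel[2]
  cz <- origin[3] + (seq_len(fine_shape[3]) - 0.5) * spec$fine_voxel[3]
  labels <- array(0L, fine_shape)
  for (s in seq_len(nrow(sp))) {
    if (r_out[s] <= 0) next
    d2 <- outer(outer((cx - sp$cx[s])^2, (cy - sp$cy[s])^2, "+"), (cz - sp$cz[s])^2, "+")
    r_in <- sp$inner_diameter[s] / 2
    inner <- d2 <= r_in^2
    wall <- d2 <= r_out[s]^2 & !inner
    labels[inner] <- 2L * s - 1L
    labels[wall] <- 2L * s
  }
  nm <- c("background", as.vector(rbind(paste0(sp$name, "_inner"), paste0(sp$name, "_wall"))))
  lab <- label_volume(labels, spec$fine_voxel, nm, origin)
  upt <- phantom_uptakes(spec)
  act <- activity_volume(array(upt[labels + 1L], fine_shape), spec$fine_voxel, origin)
  list(labels = lab, activity = act, spec = spec)
}

#' Per-label true uptakes of the sphere phantom
#' @param spec a `sphere_phantom_spec`.
#' @return named numeric vector in label order (background first).
#' @export
phantom_uptakes <- function(spec) {
  sp <- spec$spheres
  upt <- c(spec$uptake[["background"]],
           rep(c(spec$uptake[["inner"]], spec$uptake[["wall"]]), nrow(sp)))
  names(upt) <- c("background",
                  as.vector(rbind(paste0(sp$name, "_inner"), paste0(sp$name, "_wall"))))
  upt
}

#' Procedural surrogate brain atlas
#'
#' A labeled head volume standing in for a segmented MR atlas, built from
#' nested ellipsoids with volumes of the same order as human anatomy: an
#' outer skin/muscle shell, a grey-matter shell, a white-matter core, and
#' merged left+right putamen and caudate ellipsoid pairs. Labels: 0
#' background, 1 putamen, 2 caudate, 3 skin/muscle, 4 grey matter, 5 white
#' matter. This surrogate is synthetic; any user-supplied `label_volume`
#' with the same label convention can be used in its place.
#'
#' @param shape fine (MR) grid voxel counts.
#' @param voxel_size fine grid spacing in mm (default 1.1 x 1.1 x 1.4).
#' @return a `label_volume`.
#' @export
surrogate_brain_atlas <- function(shape = c(117L, 117L, 108L),
                                  voxel_size = c(1.1, 1.1, 1.4)) {
  shape <- as.integer(shape)
  voxel_size <- check_spacing(voxel_size)
  origin <- -shape * voxel_size / 2
  cx <- origin[1] + (seq_len(shape[1]) - 0.5) * voxel_size[1]
  cy <- origin[2] + (seq_len(shape[2]) - 0.5) * voxel_size[2]
  cz <- origin[3] + (seq_len(shape[3]) - 0.5) * voxel_size[3]
  inside <- function(ctr, semi) {
    outer(outer(((cx - ctr[1]) / semi[1])^2, ((cy - ctr[2]) / semi[2])^2, "+"),
          ((cz - ctr[3]) / semi[3])^2, "+") <= 1
  }
  labels <- array(0L, shape)
  labels[inside(c(0, 0, 0), c(52, 56, 62))] <- 3L      # head (skin/muscle)
  labels[inside(c(0, 2, 2), c(44, 48, 52))] <- 4L      # brain -> grey shell
  labels[inside(c(0, 2, 2), c(30, 34, 36))] <- 5L      # white matter core
  for (s in c(-1, 1)) {
    labels[inside(c(s * 22, 4, -2), c(8, 14, 9))] <- 1L   # putamen
    labels[inside(c(s * 13, 22, 4), c(7, 12, 8))] <- 2L   # caudate
  }
  label_volume(labels, voxel_size,
               c("background", "putamen", "caudate", "skin_muscle",
                 "grey_matter", "white_matter"),
               origin)
}

#' Brain phantom specification
#'
#' Relative uptakes follow striatal dopaminergic tracer imaging: putamen 4.5,
#' caudate 4.0, skin/muscle 1.0, grey matter 2.5, white matter 2.0,
#' background 0.
#'
#' @param uptake named region -> relative uptake map covering every atlas label.
#' @param pet_shape,pet_voxel PET grid.
#' @param noise_fraction,n_realizations noise model settings.
#' @return a `brain_phantom_spec` list.
#' @export
brain_phantom_spec <- function(uptake = c(background = 0, putamen = 4.5, caudate = 4.0,
                                          skin_muscle = 1.0, grey_matter = 2.5,
                                          white_matter = 2.0),
                               pet_shape = c(64L, 64L, 48L),
                               pet_voxel = c(2, 2, 3.15),
                               noise_fraction = 0.25,
                               n_realizations = 100L) {
  stopifnot(all(uptake >= 0), noise_fraction >= 0, n_realizations >= 1)
  structure(list(uptake = uptake, pet_shape = as.integer(pet_shape),
                 pet_voxel = check_spacing(pet_voxel),
                 noise_fraction = noise_fraction,
                 n_realizations = as.integer(n_realizations)),
            class = "brain_phantom_spec")
}

#' Generate the digital brain phantom
#'
#' Assigns the specified relative uptakes to the atlas regions to build the
#' ideal fine-grid activity volume (piecewise constant per VOI).
#'
#' @param spec a `brain_phantom_spec`.
#' @param atlas a labeled head `label_volume`; defaults to
#'   [surrogate_brain_atlas()].
#' @return list with `labels`, `activity`, `spec`.
#' @export
make_brain_phantom <- function(spec = brain_phantom_spec(),
                               atlas = surrogate_brain_atlas()) {
  stopifnot(inherits(spec, "brain_phantom_spec"), inherits(atlas, "label_volume"))
  missing <- setdiff(atlas$label_names, names(spec$uptake))
  if (length(missing))
    stop("uptake map missing atlas label(s): ", paste(missing, collapse = ", "))
  upt <- spec$uptake[atlas$label_names]
  act <- activity_volume(array(as.numeric(upt[atlas$labels + 1L]), dim(atlas$labels)),
                         atlas$voxel_size, atlas$origin)
  list(labels = atlas, activity = act, spec = spec)
}

#' Add stationary Gaussian noise to a volume
#'
#' Adds iid Gaussian noise, identical variance at every voxel, with standard
#' deviation `noise_fraction * reference_mean` (e.g. 25% of the mean tank
#' uptake). Deterministic for a given `rng_seed`.
#'
#' @param image `activity_volume`.
#' @param noise_fraction relative noise level (>= 0).
#' @param reference_mean reference activity (> 0).
#' @param rng_seed integer seed.
#' @return noisy `activity_volume`.
#' @export
add_noise <- function(image, noise_fraction, reference_mean = 1, rng_seed = 1L) {
  stopifnot(inherits(image, "activity_volume"), noise_fraction >= 0, reference_mean > 0)
  if (noise_fraction == 0) return(image)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  noise <- array(stats::rnorm(length(image$values), 0, noise_fraction * reference_mean),
                 dim(image$values))
  activity_volume(image$values + noise, image$voxel_size, image$origin)
}

#' Per-realization seeds derived from one master seed
#' @param master_seed integer master seed.
#' @param n number of realizations.
#' @return integer vector of n distinct seeds.
#' @export
realization_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
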