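#' Activity volume
#'
#' A real-valued 3D volume with voxel spacing in mm. This is the container for
#' ideal, blurred, reconstructed and measured PET images as well as
#' tissue-fraction masks on the PET grid.
#'
#' Coordinate convention: the physical position of the center of voxel
#' `(i, j, k)` (1-based) is `origin + (index - 0.5) * voxel_size`.
#'
#' @param values 3D numeric array.
#' @param voxel_size numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, mm offset of the corner of voxel (1,1,1).
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(values, voxel_size, origin = NULL) {
  values <- as_array3d(values)
  voxel_size <- check_spacing(voxel_size)
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  stopifnot(length(origin) == 3)
  if (!all(is.finite(values))) stop("activity values must be finite everywhere")
  structure(list(values = values, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "activity_volume")
}

#' Label volume
#'
#' An integer-labeled 3D volume on a fine (CT/MR) grid defining N
#' non-overlapping VOIs plus background. Label IDs are contiguous `0..N-1`
#' with 0 = background.
#'
#' @param labels 3D integer array.
#' @param voxel_size numeric length-3, mm.
#' @param label_names character vector naming labels `0..max(labels)`;
#'   names are the region names, in label order starting at background.
#' @param origin mm offset of the corner of voxel (1,1,1); defaults to a
#'   grid centered on the origin.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, label_names, origin = NULL) {
  labels <- as_array3d(labels)
  storage.mode(labels) <- "integer"
  voxel_size <- check_spacing(voxel_size)
  if (is.null(origin)) origin <- -dim(labels) * voxel_size / 2
  n_lab <- max(labels) + 1L
  # empty regions (e.g. a zero-diameter sphere) may leave trailing unused IDs
  if (length(label_names) < n_lab)
    stop("label_names must name labels 0..", n_lab - 1L,
         " (got ", length(label_names), " names)")
  if (anyDuplicated(label_names)) stop("region names must be unique")
  if (min(labels) < 0L) stop("labels must be >= 0")
  structure(list(labels = labels, voxel_size = voxel_size,
                 label_names = as.character(label_names),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array")
  x
}

check_spacing <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive spacings in mm")
  voxel_size
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("<activity_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = " x "), " mm\n",
      "  range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = " x "), " mm, ",
      length(x$label_names), " labels\n", sep = "")
  invisible(x)
}

#' @export
dim.activity_volume <- function(x) dim(x$values)

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Voxel volume in mm^3
#' @param vol an `activity_volume` or `label_volume`.
#' @return scalar voxel volume.
#' @export
voxel_volume <- function(vol) prod(vol$voxel_size)

#' Voxel center coordinates along one axis
#' @param vol a volume object.
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm positions of voxel centers.
#' @export
axis_coords <- function(vol, axis) {
  n <- dim(vol)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size[axis]
}

#' Target PET grid specification
#'
#' @param shape integer length-3 voxel counts.
#' @param voxel_size mm spacing, length 3.
#' @param origin mm corner offset; defaults to a centered grid.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  voxel_size <- check_spacing(voxel_size)
  if (is.null(origin)) origin <- -shape * voxel_size / 2
  structure(list(shape = shape, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Resample a fine-grid volume onto the PET grid
#'
#' Trilinear interpolation sampled at PET voxel centers. Applied to a binary
#' mask this produces tissue fractions in `[0, 1]`; the tissue-fraction
#' effect of coarse PET sampling.
#'
#' With `antialias = TRUE` the interpolation is preceded by box-average
#' prefiltering along any axis whose decimation factor exceeds 2, which makes
#' the resampled fractions volume-accurate (the total integral is preserved
#' to about 1%) at the price of smearing sub-voxel structures: thin shells
#' (e.g. 0.6 mm sphere walls) become nearly collinear with their enclosed
#' interiors, which badly conditions small transfer systems. Plain trilinear
#' (the default) keeps such regions distinguishable and is what region-based
#' PVC implementations conventionally use; the correction is self-consistent
#' either way because the same masks appear on both sides of the transfer
#' equation.
#'
#' The operation is linear and maps a constant volume to the same constant, so
#' a set of masks forming a partition of unity on the fine grid still sums to
#' one voxelwise after downsampling.
#'
#' @param vol an `activity_volume` on the fine grid (or a plain array with
#'   `voxel_size`/`origin` supplied via `activity_volume()`).
#' @param pet_grid a `grid_spec` describing the PET grid, or a length-3 voxel
#'   size in mm (grid shape then derived from the fine FOV).
#' @param antialias apply the box-average prefilter before interpolating?
#' @return `activity_volume` on the PET grid.
#' @export
downsample_to_pet <- function(vol, pet_grid, antialias = FALSE) {
  stopifnot(inherits(vol, "activity_volume"))
  if (!inherits(pet_grid, "grid_spec")) {
    vs <- check_spacing(pet_grid)
    fov <- dim(vol$values) * vol$voxel_size
    pet_grid <- grid_spec(floor(fov / vs), vs,
                          origin = vol$origin + (fov - floor(fov / vs) * vs) / 2)
  }
  if (any(pet_grid$voxel_size < vol$voxel_size - 1e-9))
    stop("upsampling (PET voxel smaller than fine voxel) is out of scope")
  decim <- pet_grid$voxel_size / vol$voxel_size
  values <- vol$values
  # box-average prefilter where the decimation factor exceeds 2 per axis
  for (ax in 1:3) {
    if (antialias && decim[ax] > 2) {
      k <- max(1L, round(decim[ax]))
      # centered box of width k fine voxels; even k gets half-weight ends
      kern <- if (k %% 2L == 1L) rep(1 / k, k)
              else c(0.5 / k, rep(1 / k, k - 1L), 0.5 / k)
      values <- .conv_axis_cpp(values, dim(values), kern, ax - 1L, TRUE)
    }
  }
  # fractional fine-grid indices of PET voxel centers
  ctr <- lapply(1:3, function(ax) {
    pos <- pet_grid$origin[ax] + (seq_len(pet_grid$shape[ax]) - 0.5) * pet_grid$voxel_size[ax]
    (pos - vol$origin[ax]) / vol$voxel_size[ax] + 0.5
  })
  idx <- expand_indices(pet_grid$shape)
  out <- .trilinear_cpp(values, dim(values),
                        ctr[[1]][idx$i], ctr[[2]][idx$j], ctr[[3]][idx$k])
  dim(out) <- pet_grid$shape
  activity_volume(out, pet_grid$voxel_size, pet_grid$origin)
}

expand_indices <- function(shape) {
  list(i = rep.int(seq_len(shape[1]), prod(shape[2:3])),
       j = rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
       k = rep(seq_len(shape[3]), each = prod(shape[1:2])))
}

#' Shift a label volume by a physical offset
#'
#' Translates the labels by the nearest integer number of fine voxels per
#' axis; voxels shifted in from outside the grid take the background label
#' (0). Used to emulate CT/MR-to-PET misregistration before tissue-fraction
#' downsampling. Shifts beyond 10 mm on any axis trigger a warning (the range
#' studied for misregistration robustness).
#'
#' @param labels a `label_volume`.
#' @param shift_mm numeric length-3 shift in mm.
#' @return shifted `label_volume`.
#' @export
shift_labels <- function(labels, shift_mm) {
  stopifnot(inherits(labels, "label_volume"), length(shift_mm) == 3)
  if (any(abs(shift_mm) > 10))
    warning("shift exceeds the 10 mm misregistration range")
  nvox <- round(shift_mm / labels$voxel_size)
  arr <- labels$labels
  d <- dim(arr)
  out <- array(0L, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]; s <- nvox[ax]
    dst[[ax]] <- seq_len(n)[(seq_len(n) - s) >= 1 & (seq_len(n) - s) <= n]
    src[[ax]] <- dst[[ax]] - s
    if (length(dst[[ax]]) == 0L) {
      return(label_volume(out, labels$voxel_size, labels$label_names, labels$origin))
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  label_volume(out, labels$voxel_size, labels$label_names, labels$origin)
}

#' Binary fine-grid masks for each label
#'
#' @param labels a `label_volume`.
#' @param drop_background drop label 0 from the result?
#' @return named list of `activity_volume` binary masks (one per label).
#' @export
label_masks <- function(labels, drop_background = FALSE) {
  stopifnot(inherits(labels, "label_volume"))
  ids <- seq_along(labels$label_names) - 1L
  if (drop_background) ids <- ids[-1]
  out <- lapply(ids, function(id) {
    activity_volume(array(as.numeric(labels$labels == id), dim(labels$labels)),
                    labels$voxel_size, labels$origin)
  })
  names(out) <- labels$label_names[ids + 1L]
  out
}

#' Tissue-fraction masks on the PET grid
#'
#' Downsamples each label's binary mask to the PET grid. The result is a
#' voxelwise partition of unity (fractions sum to 1) because downsampling is
#' linear and preserves constants.
#'
#' @param labels a `label_volume` (fine grid).
#' @param pet_grid a `grid_spec`.
#' @param antialias see [downsample_to_pet()].
#' @return named list of `activity_volume` tissue-fraction masks.
#' @export
pet_masks <- function(labels, pet_grid, antialias = FALSE) {
  masks <- label_masks(labels)
  lapply(masks, downsample_to_pet, pet_grid = pet_grid, antialias = antialias)
}

#' Separable 3D Gaussian blur of a volume
#'
#' Convolution with a normalized separable Gaussian, replicate-edge padding
#' (so constants are preserved exactly, which keeps mask partitions of unity
#' intact at the FOV border).
#'
#' @param vol `activity_volume`.
#' @param fwhm_mm length-3 FWHM in mm (`sigma = FWHM / (2 sqrt(2 log 2))`).
#' @return blurred `activity_volume`.
#' @export
gaussian_blur <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "activity_volume"))
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  sigma <- fwhm_to_sigma(fwhm_mm)
  values <- vol$values
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    kern <- gauss_kernel(sigma[ax] / vol$voxel_size[ax])
    values <- .conv_axis_cpp(values, dim(values), kern, ax - 1L, TRUE)
  }
  activity_volume(values, vol$voxel_size, vol$origin)
}

#' @rdname gaussian_blur
#' @param fwhm FWHM values (mm).
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname gaussian_blur
#' @param sigma standard deviations (mm).
#' @export
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

gauss_kernel <- function(sigma_vox, half_width = NULL) {
  if (is.null(half_width)) half_width <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}
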