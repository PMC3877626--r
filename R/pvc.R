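#' Regional spread functions
#'
#' One volume per VOI: the PET image a region of unit uptake would produce
#' through the scanner's resolution model. Image-space RSFs (GTM/sGTM) are
#' 3D Gaussian convolutions of the tissue-fraction masks and lie in
#' `[0, 1]`; sinogram-space RSFs (GTMo/sGTMo) come from
#' project--blur--reconstruct and may contain negative values and streak
#' artifacts from the reconstruction -- these are retained, not clipped.
#'
#' @param rsfs named list of `activity_volume`s on the PET grid.
#' @param method_tag "image-space" or "sinogram-space".
#' @return an `rsf_set`.
#' @export
rsf_set <- function(rsfs, method_tag) {
  stopifnot(is.list(rsfs), length(rsfs) >= 1, !is.null(names(rsfs)))
  structure(list(rsfs = rsfs, region_names = names(rsfs),
                 method_tag = match.arg(method_tag, c("image-space", "sinogram-space"))),
            class = "rsf_set")
}

#' @export
print.rsf_set <- function(x, ...) {
  cat("<rsf_set> ", length(x$rsfs), " ", x$method_tag, " RSFs: ",
      paste(x$region_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

assert_partition <- function(masks, tol, what = "masks") {
  total <- Reduce(`+`, lapply(masks, function(m) m$values))
  dev <- max(abs(total - 1))
  if (dev > tol)
    stop(what, " are not a partition of unity: max |sum - 1| = ",
         signif(dev, 4), " exceeds tolerance ", tol)
  invisible(dev)
}

#' Image-space regional spread functions
#'
#' Convolves each PET-grid tissue-fraction mask with a normalized separable
#' 3D Gaussian PSF (replicate-edge padding). Because convolution is linear
#' and preserves constants, an exact mask partition of unity survives: the
#' RSFs sum to one voxelwise to floating-point accuracy.
#'
#' @param masks named list of tissue-fraction `activity_volume`s on the PET
#'   grid, summing to 1 voxelwise.
#' @param psf_fwhm length-3 PSF FWHM in mm.
#' @param partition_tol tolerance on the mask partition check; set
#'   `check_partition = FALSE` for deliberately partial mask sets (e.g. a
#'   per-sphere subsystem).
#' @param check_partition verify the masks partition the FOV?
#' @return an `rsf_set` (image-space).
#' @export
compute_rsf_image_space <- function(masks, psf_fwhm, partition_tol = 1e-6,
                                    check_partition = TRUE) {
  stopifnot(is.list(masks), length(masks) >= 1)
  if (check_partition) assert_partition(masks, partition_tol)
  rsf_set(lapply(masks, gaussian_blur, fwhm_mm = psf_fwhm), "image-space")
}

#' Sinogram-space regional spread functions
#'
#' Each tissue-fraction mask is forward projected, blurred in sinogram space
#' with the calibrated Gaussian, and reconstructed by FBP -- the same system
#' model applied to simulated PET images, so that both sides of the transfer
#' equation see the same system. The voxelwise sum of the RSFs over a full
#' VOI partition is checked against unity (default tolerance 0.5%, the
#' conventional acceptance level for this check); negative voxel values are
#' expected and retained.
#'
#' @param masks named list of PET-grid tissue-fraction masks.
#' @param blur a calibrated `blur_model`.
#' @param geometry the `projection_geometry` shared with the PET simulation.
#' @param partition_tol voxelwise tolerance on the RSF sum (default 0.005).
#' @param check_partition verify Eq.-(4)-style partition of unity?
#' @return an `rsf_set` (sinogram-space).
#' @export
compute_rsf_sinogram_space <- function(masks, blur, geometry,
                                       partition_tol = 0.005,
                                       check_partition = TRUE) {
  stopifnot(is.list(masks), length(masks) >= 1, inherits(blur, "blur_model"))
  rsfs <- lapply(masks, simulate_acquisition, blur = blur, geometry = geometry)
  if (check_partition) {
    total <- Reduce(`+`, lapply(rsfs, function(m) m$values))
    dev <- max(abs(total - 1))
    if (dev > partition_tol)
      stop("sinogram-space RSFs deviate from unity: max |sum - 1| = ",
           signif(dev, 4), " exceeds tolerance ", partition_tol)
  }
  rsf_set(rsfs, "sinogram-space")
}

#' Transfer system (GTM family)
#'
#' The linear system `W T = t` of region-based PVC: `W[j, i]` is the
#' integral of source region i's RSF over sampling region j, `t[j]` the
#' PET image sampled over region j, and `T` the corrected regional uptakes.
#' For GTM/GTMo the sampling regions are the sharp tissue-fraction VOIs; for
#' sGTM/sGTMo they are the RSFs themselves, which makes `W` symmetric.
#'
#' @param omega the N x N weighting matrix (rows: sampling regions, columns:
#'   source regions).
#' @param t sampled vector.
#' @param method one of "GTM", "sGTM", "GTMo", "sGTMo".
#' @param region_names source region names.
#' @return a `transfer_system` (class `pvc_fit` once solved).
#' @export
transfer_system <- function(omega, t, method, region_names = rownames(omega)) {
  stopifnot(is.matrix(omega), nrow(omega) == ncol(omega), length(t) == nrow(omega),
            all(is.finite(omega)))
  structure(list(omega = omega, t = as.numeric(t), T = NULL,
                 condition_number = NA_real_,
                 method = match.arg(method, c("GTM", "sGTM", "GTMo", "sGTMo")),
                 region_names = region_names),
            class = "transfer_system")
}

as_matrix_cols <- function(vols) {
  vapply(vols, function(v) as.numeric(v$values), numeric(length(vols[[1]]$values)))
}

#' Build the GTM / GTMo transfer system
#'
#' `W[j, i] = sum_r RSF_i(r) VOI_j(r) dv` and `t_j = sum_r I(r) VOI_j(r) dv`
#' (voxel sums times voxel volume; the scaling cancels in the solve but both
#' sides use the same convention). Sampling VOIs default to the source masks;
#' a different sampling set (e.g. a local background cylinder) may be given.
#'
#' @param rsfs an `rsf_set` of the N source regions.
#' @param masks named list of N tissue-fraction sampling VOIs on the PET grid.
#' @param pet_image measured/simulated PET `activity_volume`.
#' @return an unsolved `transfer_system` with method GTM or GTMo depending on
#'   the RSF space.
#' @export
build_system_gtm <- function(rsfs, masks, pet_image) {
  stopifnot(inherits(rsfs, "rsf_set"), length(masks) == length(rsfs$rsfs))
  build_system_weighted(rsfs, masks, pet_image,
                        if (rsfs$method_tag == "image-space") "GTM" else "GTMo")
}

# Shared core: W[j, i] = sum_r RSF_i(r) w_j(r) dv, t_j = sum_r I(r) w_j(r) dv
# for arbitrary sampling functions w_j (sharp VOIs, RSFs, or domain-restricted
# RSFs for local subsystem analyses).
build_system_weighted <- function(rsfs, sampling, pet_image, method) {
  check_same_grid(c(rsfs$rsfs, sampling, list(pet_image)))
  dv <- voxel_volume(pet_image)
  R <- as_matrix_cols(rsfs$rsfs)
  M <- as_matrix_cols(sampling)
  omega <- crossprod(M, R) * dv            # rows: sampling j, cols: source i
  t <- as.numeric(crossprod(M, as.numeric(pet_image$values))) * dv
  dimnames(omega) <- list(names(sampling) %||% rsfs$region_names, rsfs$region_names)
  transfer_system(omega, t, method, rsfs$region_names)
}

#' Build the sGTM / sGTMo transfer system
#'
#' Symmetric variant: the PET image is sampled with the RSFs themselves
#' (blurry boundaries) rather than the sharp VOIs:
#' `W[j, i] = sum_r RSF_i(r) RSF_j(r) dv`, `t_j = sum_r I(r) RSF_j(r) dv`.
#' `W` is a Gram matrix -- symmetric, and positive semidefinite for
#' image-space RSFs.
#'
#' For a local subsystem analysis (e.g. one sphere with its background
#' cylinder) `domain` restricts both integrals to the local region:
#' `W[j, i] = sum_{r in domain} RSF_i RSF_j dv`, which stays symmetric.
#'
#' @param rsfs an `rsf_set`.
#' @param pet_image `activity_volume`.
#' @param domain optional 0/1 `activity_volume` defining the integration
#'   domain (default: whole FOV).
#' @return an unsolved `transfer_system` (sGTM or sGTMo).
#' @export
build_system_sgtm <- function(rsfs, pet_image, domain = NULL) {
  stopifnot(inherits(rsfs, "rsf_set"))
  check_same_grid(c(rsfs$rsfs, list(pet_image)))
  dv <- voxel_volume(pet_image)
  R <- as_matrix_cols(rsfs$rsfs)
  M <- if (is.null(domain)) R
       else R * as.numeric(domain$values)    # integrals over the local domain
  omega <- crossprod(M, R) * dv
  omega <- (omega + t(omega)) / 2           # enforce exact symmetry
  t <- as.numeric(crossprod(M, as.numeric(pet_image$values))) * dv
  dimnames(omega) <- list(rsfs$region_names, rsfs$region_names)
  transfer_system(omega, t,
                  if (rsfs$method_tag == "image-space") "sGTM" else "sGTMo",
                  rsfs$region_names)
}

check_same_grid <- function(vols) {
  d <- lapply(vols, function(v) dim(v$values))
  vs <- lapply(vols, function(v) v$voxel_size)
  if (length(unique(vapply(d, paste, character(1), collapse = "x"))) != 1 ||
      max(abs(do.call(rbind, vs) - rep(vs[[1]], each = length(vs)))) > 1e-9)
    stop("grid mismatch: all volumes must share the PET grid")
  invisible(TRUE)
}

#' Solve a transfer system
#'
#' Direct dense LU solve of `W T = t` (no explicit matrix inversion, no
#' regularization by default, matching plain inversion of the weighting
#' matrix). The condition number is recorded and a warning emitted above the
#' threshold. An optional ridge term is available for ill-conditioned cases.
#'
#' @param system an unsolved `transfer_system`.
#' @param condition_warn warn when the 2-norm condition number exceeds this.
#' @param ridge optional Tikhonov term added to the diagonal (default 0).
#' @return the system with corrected uptakes `T`, as a `pvc_fit`.
#' @export
solve_pvc <- function(system, condition_warn = 1e6, ridge = 0) {
  stopifnot(inherits(system, "transfer_system"))
  omega <- system$omega
  if (ridge > 0) omega <- omega + diag(ridge, nrow(omega))
  system$condition_number <- kappa(omega, exact = TRUE)
  if (system$condition_number > condition_warn)
    warning("transfer matrix condition number ", signif(system$condition_number, 3),
            " exceeds ", condition_warn)
  T <- tryCatch(solve(omega, system$t),
                error = function(e)
                  stop("singular transfer matrix (", conditionMessage(e),
                       "); consider merging regions", call. = FALSE))
  system$T <- as.numeric(T)
  names(system$T) <- system$region_names
  class(system) <- c("pvc_fit", "transfer_system")
  system
}

#' @export
print.transfer_system <- function(x, ...) {
  cat("<", paste(class(x)[1]), "> method ", x$method, ", ",
      nrow(x$omega), " regions", sep = "")
  if (!is.null(x$T))
    cat("; condition number ", signif(x$condition_number, 3), "\n",
        paste(sprintf("  %-18s t = %10.4g  T = %10.4g", x$region_names, x$t, x$T),
              collapse = "\n"), sep = "")
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved transfer system
#'
#' @param x a `pvc_fit`.
#' @param ... unused.
#' @return tibble with one row per region: sampled value `t`, corrected
#'   uptake `T`, and the diagonal self-weight.
#' @export
tidy.pvc_fit <- function(x, ...) {
  tibble::tibble(region = x$region_names,
                 sampled = unname(x$t),
                 corrected = unname(x$T),
                 self_weight = unname(diag(x$omega)))
}

#' Glance at a solved transfer system
#' @param x a `pvc_fit`.
#' @param ... unused.
#' @return one-row tibble: method, region count, condition number, residual.
#' @export
glance.pvc_fit <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_regions = nrow(x$omega),
                 condition_number = x$condition_number,
                 max_residual = max(abs(x$omega %*% x$T - x$t)))
}

#' End-to-end region-based partial volume correction
#'
#' Orchestrates the full correction for one or more methods: downsamples the
#' fine-grid label masks to PET tissue fractions, computes the appropriate
#' RSF set (image-space RSFs are shared between GTM and sGTM, sinogram-space
#' RSFs between GTMo and sGTMo -- each set is computed once), builds the
#' requested systems over the joint N x N region partition, and solves them.
#'
#' @param pet_image measured/simulated PET `activity_volume`.
#' @param labels_fine fine-grid `label_volume` of the VOIs.
#' @param method character vector from `c("GTM", "sGTM", "GTMo", "sGTMo")`.
#' @param psf_fwhm length-3 PSF FWHM in mm (required for GTM/sGTM).
#' @param blur calibrated `blur_model` (required for GTMo/sGTMo).
#' @param geometry `projection_geometry` (required for GTMo/sGTMo).
#' @param masks optional precomputed PET-grid tissue-fraction masks.
#' @param binarize sample with 0/1 masks (fraction > 0.5) instead of
#'   fractional masks for the GTM/GTMo t-vector.
#' @return a single `pvc_fit` when one method is requested, else a named
#'   list of `pvc_fit`s (with shared RSF sets attached as attribute
#'   `"rsf_sets"`).
#' @export
apply_pvc <- function(pet_image, labels_fine, method = "GTM",
                      psf_fwhm = NULL, blur = NULL, geometry = NULL,
                      masks = NULL, binarize = FALSE) {
  method <- match.arg(method, c("GTM", "sGTM", "GTMo", "sGTMo"), several.ok = TRUE)
  if (is.null(masks)) {
    pg <- grid_spec(dim(pet_image$values), pet_image$voxel_size, pet_image$origin)
    masks <- pet_masks(labels_fine, pg)
  }
  sampling <- masks
  if (binarize)
    sampling <- lapply(masks, function(m)
      activity_volume(array(as.numeric(m$values > 0.5), dim(m$values)),
                      m$voxel_size, m$origin))
  rsf_sets <- list()
  if (any(method %in% c("GTM", "sGTM"))) {
    if (is.null(psf_fwhm)) stop("psf_fwhm is required for image-space methods")
    rsf_sets[["image-space"]] <- compute_rsf_image_space(masks, psf_fwhm)
  }
  if (any(method %in% c("GTMo", "sGTMo"))) {
    if (is.null(blur) || is.null(geometry))
      stop("a calibrated blur model and geometry are required for sinogram-space methods")
    rsf_sets[["sinogram-space"]] <- compute_rsf_sinogram_space(masks, blur, geometry)
  }
  fits <- lapply(method, function(m) {
    rs <- rsf_sets[[if (m %in% c("GTM", "sGTM")) "image-space" else "sinogram-space"]]
    sys <- if (m %in% c("GTM", "GTMo")) build_system_gtm(rs, sampling, pet_image)
           else build_system_sgtm(rs, pet_image)
    solve_pvc(sys)
  })
  names(fits) <- method
  if (length(fits) == 1L) return(fits[[1]])
  attr(fits, "rsf_sets") <- rsf_sets
  fits
}
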