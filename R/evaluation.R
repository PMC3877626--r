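#' Recovery coefficient
#'
#' Ratio of measured to true activity within a VOI; ideal value 1. For
#' zero-uptake regions (cold sphere walls, the brain background) the RC is
#' undefined and `NA` is returned -- the harness reports the absolute
#' corrected uptake for those regions instead.
#'
#' @param measured measured (or corrected) activity.
#' @param truth true activity.
#' @return `measured / truth`, or `NA` where `truth == 0`.
#' @export
recovery_coefficient <- function(measured, truth) {
  out <- measured / truth
  out[rep_len(truth == 0, length(out))] <- NA_real_
  out
}

#' Noise magnification factor
#'
#' Ratio of the coefficient of variation after PVC to that before PVC,
#' computed across noise realizations: `NMF = CV(T_i) / CV(t_i)` with
#' `CV = sd / |mean|`. Ideal value 1; PVC usually amplifies noise, so values
#' above 1 are typical. The pre-PVC samples `t_i` are the method's own raw
#' samples (mask-weighted for GTM/GTMo, RSF-weighted for sGTM/sGTMo).
#'
#' @param T_samples corrected uptakes per realization.
#' @param t_samples raw sampled values per realization.
#' @return scalar NMF.
#' @export
noise_magnification <- function(T_samples, t_samples) {
  if (length(T_samples) < 2 || length(t_samples) < 2)
    stop("at least 2 realizations are required to estimate the NMF")
  cv <- function(x) stats::sd(x) / abs(mean(x))
  cv(T_samples) / cv(t_samples)
}

#' Per-sphere 3x3 correction systems for the sphere phantom
#'
#' Following the per-sphere analysis design, each sphere is corrected with
#' its own 3x3 system. The three source regions are the sphere interior, the
#' sphere wall, and the full background label; the three sampling VOIs are
#' the interior, the wall, and the background restricted to a local cylinder
#' extending `background_margin` mm (at least 20) beyond the outer wall.
#' Restricting only the sampling region keeps the system local (neighbouring
#' spheres contribute negligibly) without misattributing background spill at
#' the artificial cylinder boundary.
#'
#' @param phantom result of [make_sphere_phantom()].
#' @param masks PET-grid tissue-fraction masks from [pet_masks()] (full
#'   partition, background first).
#' @return list per sphere: `name`, `source_names` (indices into `masks`),
#'   `sampling` (list of 3 sampling VOIs), `truth` (true uptakes).
#' @export
sphere_subsystems <- function(phantom, masks) {
  spec <- phantom$spec
  sp <- spec$spheres
  bg <- masks[["background"]]
  pg <- grid_spec(dim(bg$values), bg$voxel_size, bg$origin)
  cx <- pg$origin[1] + (seq_len(pg$shape[1]) - 0.5) * pg$voxel_size[1]
  cy <- pg$origin[2] + (seq_len(pg$shape[2]) - 0.5) * pg$voxel_size[2]
  cz <- pg$origin[3] + (seq_len(pg$shape[3]) - 0.5) * pg$voxel_size[3]
  upt <- spec$uptake
  lapply(seq_len(nrow(sp)), function(s) {
    r_cyl <- sp$inner_diameter[s] / 2 + sp$wall[s] + spec$background_margin
    in_r <- outer((cx - sp$cx[s])^2, (cy - sp$cy[s])^2, "+") <= r_cyl^2
    in_z <- abs(cz - sp$cz[s]) <= r_cyl
    cyl <- array(outer(as.numeric(in_r), as.numeric(in_z)), pg$shape)
    nm_in <- paste0(sp$name[s], "_inner"); nm_wl <- paste0(sp$name[s], "_wall")
    local_bg <- activity_volume(bg$values * cyl, bg$voxel_size, bg$origin)
    list(name = sp$name[s],
         source_names = c(nm_in, nm_wl, "background"),
         sampling = stats::setNames(list(masks[[nm_in]], masks[[nm_wl]], local_bg),
                                    c(nm_in, nm_wl, "background")),
         domain = activity_volume(cyl, bg$voxel_size, bg$origin),
         truth = c(upt[["inner"]], upt[["wall"]], upt[["background"]]))
  })
}

#' Precompute the correction model for an evaluation run
#'
#' Computes everything that does not depend on the noise realization: the
#' PET-grid tissue-fraction masks, both RSF sets, the noise-free simulated
#' PET images for the image-space and sinogram-space method families
#' (each family is evaluated on its matched system model), and the
#' per-system weighting matrices.
#'
#' @param phantom a sphere or brain phantom (list with `labels`, `activity`,
#'   `spec`).
#' @param psf_fwhm length-3 PSF FWHM in mm for GTM/sGTM and the matched
#'   image-space simulation.
#' @param blur calibrated `blur_model` for GTMo/sGTMo.
#' @param geometry `projection_geometry`.
#' @param per_sphere use per-sphere 3x3 systems (sphere phantom only)?
#' @param spheres optional subset of sphere names: only those subsystems (and
#'   the RSFs they need) are computed.
#' @param simulate_images simulate the noise-free PET images? Set `FALSE`
#'   when the model is rebuilt for shifted masks and the images are reused.
#' @return a `pvc_model` list used by the experiment runners.
#' @export
precompute_model <- function(phantom, psf_fwhm, blur, geometry, per_sphere = FALSE,
                             spheres = NULL, simulate_images = TRUE) {
  pg <- geometry$pet_grid
  masks <- pet_masks(phantom$labels, pg)
  ideal_pet <- downsample_to_pet(phantom$activity, pg)
  truth <- region_truth(phantom)
  systems <- if (per_sphere) {
    sphere_subsystems(phantom, masks)
  } else {
    list(list(name = "joint", source_names = names(masks),
              sampling = masks, truth = truth[names(masks)]))
  }
  if (!is.null(spheres)) {
    systems <- systems[vapply(systems, `[[`, "", "name") %in% spheres]
    if (!length(systems)) stop("no subsystem matches the requested sphere names")
  }
  needed <- unique(unlist(lapply(systems, `[[`, "source_names")))
  full <- setequal(needed, names(masks))
  rsf_is <- compute_rsf_image_space(masks[needed], psf_fwhm, check_partition = full)
  rsf_os <- compute_rsf_sinogram_space(masks[needed], blur, geometry,
                                       check_partition = full)
  img_is <- if (simulate_images) gaussian_blur(ideal_pet, psf_fwhm)
  img_os <- if (simulate_images) simulate_acquisition(ideal_pet, blur, geometry)
  structure(list(masks = masks, ideal_pet = ideal_pet,
                 img_is = img_is, img_os = img_os,
                 rsf_is = rsf_is, rsf_os = rsf_os,
                 systems = systems, truth = truth,
                 psf_fwhm = psf_fwhm, blur = blur, geometry = geometry,
                 noise_reference = noise_reference(phantom, ideal_pet)),
            class = "pvc_model")
}

region_truth <- function(phantom) {
  if (inherits(phantom$spec, "sphere_phantom_spec")) phantom_uptakes(phantom$spec)
  else phantom$spec$uptake[phantom$labels$label_names]
}

noise_reference <- function(phantom, ideal_pet) {
  if (inherits(phantom$spec, "sphere_phantom_spec")) {
    phantom$spec$uptake[["background"]]      # mean tank uptake
  } else {
    # brain: background uptake is zero, use the mean uptake over the head
    v <- ideal_pet$values
    mean(v[v > 0.05])
  }
}

method_family <- function(method) {
  ifelse(method %in% c("GTM", "sGTM"), "image-space", "sinogram-space")
}

# Solve every (method, system) for one PET image; returns tibble rows.
solve_all <- function(model, images, methods, keep_omega = FALSE) {
  purrr::map_dfr(model$systems, function(su) {
    purrr::map_dfr(methods, function(m) {
      fam <- method_family(m)
      rs <- if (fam == "image-space") model$rsf_is else model$rsf_os
      rs_sub <- rsf_set(rs$rsfs[su$source_names], rs$method_tag)
      img <- if (fam == "image-space") images$is else images$os
      sys <- if (m %in% c("GTM", "GTMo")) {
        build_system_gtm(rs_sub, su$sampling, img)
      } else {
        build_system_sgtm(rs_sub, img, domain = su$domain)
      }
      fit <- solve_pvc(sys, condition_warn = Inf)
      out <- tibble::tibble(system = su$name, method = m,
                            region = su$source_names,
                            truth = as.numeric(su$truth),
                            sampled = fit$t, corrected = fit$T,
                            condition_number = fit$condition_number)
      if (keep_omega) out$omega <- rep(list(fit$omega), nrow(out))
      out
    })
  })
}

# Translate an activity volume by a physical offset (trilinear resampling on
# its own grid, replicate edges).
shift_image <- function(img, shift_mm) {
  d <- dim(img$values)
  idx <- expand_indices(d)
  off <- shift_mm / img$voxel_size
  out <- .trilinear_cpp(img$values, d,
                        idx$i - off[1], idx$j - off[2], idx$k - off[3])
  dim(out) <- d
  activity_volume(out, img$voxel_size, img$origin)
}

#' Monte-Carlo accuracy experiment
#'
#' Simulates `n_realizations` noisy PET images (stationary Gaussian noise,
#' std = `noise_fraction` x reference mean, one independent field per
#' realization shared by all methods), applies each requested PVC method on
#' its matched system model, and summarizes recovery coefficients per
#' (method, region): mean and standard deviation of the RC across
#' realizations, the noise magnification factor, and the absolute corrected
#' uptake for zero-uptake regions.
#'
#' @param phantom sphere or brain phantom list.
#' @param model a `pvc_model` from [precompute_model()]; built on the fly if
#'   `NULL`.
#' @param methods methods to evaluate.
#' @param n_realizations number of noise realizations (>= 1).
#' @param noise_fraction relative noise level; defaults to the phantom spec.
#' @param seed master seed spawning one sub-seed per realization.
#' @param psf_fwhm,blur,geometry passed to [precompute_model()] when `model`
#'   is `NULL`.
#' @param per_sphere per-sphere 3x3 systems (sphere phantom)?
#' @return a `pvc_experiment` tibble: one row per (system, method, region)
#'   with columns `truth`, `rc_mean`, `rc_sd`, `nmf`, `corrected_mean`,
#'   `n_realizations`; per-realization draws in attribute `"draws"`.
#' @export
run_accuracy_experiment <- function(phantom, model = NULL,
                                    methods = c("GTM", "sGTM", "GTMo", "sGTMo"),
                                    n_realizations = 50L,
                                    noise_fraction = NULL,
                                    seed = 1L,
                                    psf_fwhm = NULL, blur = NULL, geometry = NULL,
                                    per_sphere = inherits(phantom$spec, "sphere_phantom_spec")) {
  stopifnot(n_realizations >= 1)
  if (is.null(model))
    model <- precompute_model(phantom, psf_fwhm, blur, geometry, per_sphere = per_sphere)
  if (is.null(noise_fraction)) noise_fraction <- phantom$spec$noise_fraction
  seeds <- realization_seeds(seed, n_realizations)
  draws <- purrr::map_dfr(seq_len(n_realizations), function(r) {
    if (noise_fraction > 0) {
      noisy_is <- add_noise(model$img_is, noise_fraction, model$noise_reference, seeds[r])
      noise <- noisy_is$values - model$img_is$values
      noisy_os <- activity_volume(model$img_os$values + noise,
                                  model$img_os$voxel_size, model$img_os$origin)
    } else {
      noisy_is <- model$img_is; noisy_os <- model$img_os
    }
    out <- solve_all(model, list(is = noisy_is, os = noisy_os), methods)
    out$realization <- r
    out
  })
  summ <- draws |>
    dplyr::group_by(.data$system, .data$method, .data$region) |>
    dplyr::summarise(
      truth = .data$truth[1],
      rc_mean = mean(recovery_coefficient(.data$corrected, .data$truth)),
      rc_sd = stats::sd(recovery_coefficient(.data$corrected, .data$truth)),
      corrected_mean = mean(.data$corrected),
      corrected_sd = stats::sd(.data$corrected),
      nmf = if (dplyr::n() >= 2 && abs(mean(.data$sampled)) > 0 &&
                abs(mean(.data$corrected)) > 0)
        noise_magnification(.data$corrected, .data$sampled) else NA_real_,
      n_realizations = dplyr::n(),
      .groups = "drop")
  attr(summ, "draws") <- draws
  attr(summ, "config") <- list(methods = methods, n_realizations = n_realizations,
                               noise_fraction = noise_fraction, seed = seed,
                               per_sphere = per_sphere)
  class(summ) <- c("pvc_experiment", class(summ))
  summ
}

#' Misregistration robustness experiment
#'
#' For each shift, translates the fine-grid labels (nearest fine voxel),
#' re-downsamples the tissue fractions, recomputes the RSFs and the full
#' correction against the fixed PET image, and reports the recovery
#' coefficient normalized to its zero-shift value. Shifts are applied one
#' axis at a time. With `recompute_rsfs = FALSE` the RSFs and weighting
#' matrices from zero shift are reused and only the GTM/GTMo sampling masks
#' move: in that mode the weighting matrices are bitwise identical across
#' shifts -- registration errors enter only through the sampled values.
#'
#' @param phantom phantom list (sphere or brain).
#' @param model optional precomputed `pvc_model` (noise-free images reused).
#' @param methods methods to evaluate.
#' @param shifts_mm numeric vector of shifts (0 is added if absent).
#' @param axis "x", "y" or "z".
#' @param recompute_rsfs recompute masks/RSFs from the shifted labels
#'   (default), or hold them fixed and shift only the sampling masks.
#' @param spheres optional subset of sphere names to analyze (saves the RSF
#'   recomputation for the others at every shift).
#' @param psf_fwhm,blur,geometry,per_sphere as in [run_accuracy_experiment()].
#' @return a `pvc_shift_experiment` tibble: (system, method, region, shift,
#'   rc, rc_norm).
#' @export
run_misregistration_experiment <- function(phantom, model = NULL,
                                           methods = c("GTMo", "sGTMo"),
                                           shifts_mm = c(0, 2, 4, 6, 8, 10),
                                           axis = "x",
                                           recompute_rsfs = TRUE,
                                           spheres = NULL,
                                           psf_fwhm = NULL, blur = NULL, geometry = NULL,
                                           per_sphere = inherits(phantom$spec, "sphere_phantom_spec")) {
  axis_i <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (!0 %in% shifts_mm) shifts_mm <- c(0, shifts_mm)
  shifts_mm <- sort(unique(shifts_mm))
  if (is.null(model))
    model <- precompute_model(phantom, psf_fwhm, blur, geometry,
                              per_sphere = per_sphere, spheres = spheres)
  if (per_sphere && inherits(phantom$spec, "sphere_phantom_spec")) {
    have <- vapply(model$systems, `[[`, "", "name")
    want <- spheres %||% phantom$spec$spheres$name
    if (!all(want %in% have))
      model$systems <- sphere_subsystems(phantom, model$masks)
  }
  if (!is.null(spheres))
    model$systems <- model$systems[vapply(model$systems, `[[`, "", "name") %in% spheres]
  if (!length(model$systems)) stop("no subsystem matches the requested sphere names")
  images <- list(is = model$img_is, os = model$img_os)
  pg <- model$geometry$pet_grid
  base_rows <- NULL
  rows <- purrr::map_dfr(shifts_mm, function(sh) {
    vec <- c(0, 0, 0); vec[axis_i] <- sh
    if (sh == 0) {
      shifted_model <- model
    } else if (recompute_rsfs) {
      lab_s <- shift_labels(phantom$labels, vec)
      phantom_s <- list(labels = lab_s, activity = phantom$activity, spec = phantom$spec)
      shifted_model <- precompute_model(phantom_s, model$psf_fwhm, model$blur,
                                        model$geometry, per_sphere = per_sphere,
                                        spheres = spheres, simulate_images = FALSE)
      if (per_sphere) {
        # the local cylinders follow the (shifted) CT geometry
        sp <- phantom$spec$spheres
        sp$cx <- sp$cx + vec[1]; sp$cy <- sp$cy + vec[2]; sp$cz <- sp$cz + vec[3]
        spec_s <- phantom$spec; spec_s$spheres <- sp
        sys_s <- sphere_subsystems(list(spec = spec_s), shifted_model$masks)
        if (!is.null(spheres))
          sys_s <- sys_s[vapply(sys_s, `[[`, "", "name") %in% spheres]
        shifted_model$systems <- sys_s
      }
      # the PET image is the unshifted acquisition
      shifted_model$img_is <- model$img_is
      shifted_model$img_os <- model$img_os
    } else {
      # hold every CT-derived object (masks, RSFs, weighting matrices) fixed
      # and displace the PET image by the opposite offset instead -- the same
      # relative misregistration; registration errors then enter the solve
      # only through the sampled t values.
      shifted_model <- model
    }
    imgs <- if (sh == 0 || recompute_rsfs) images
            else list(is = shift_image(images$is, -vec),
                      os = shift_image(images$os, -vec))
    out <- solve_all(shifted_model, imgs, methods, keep_omega = TRUE)
    out$shift <- sh
    out
  })
  base <- rows |> dplyr::filter(.data$shift == 0) |>
    dplyr::select("system", "method", "region", rc0 = "corrected")
  summ <- rows |>
    dplyr::left_join(base, by = c("system", "method", "region")) |>
    dplyr::mutate(rc = recovery_coefficient(.data$corrected, .data$truth),
                  rc_norm = .data$corrected / .data$rc0) |>
    dplyr::select("system", "method", "region", "shift", "truth",
                  "corrected", "rc", "rc_norm")
  attr(summ, "axis") <- axis
  attr(summ, "recompute_rsfs") <- recompute_rsfs
  attr(summ, "rows") <- rows
  class(summ) <- c("pvc_shift_experiment", class(summ))
  summ
}

#' Plot an accuracy experiment
#'
#' Mean recovery coefficient per region and method with +-1 sd error bars
#' across noise realizations (nonzero-uptake regions only).
#'
#' @param object a `pvc_experiment`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pvc_experiment <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$rc_mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$rc_mean,
                                   colour = .data$method, group = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rc_mean - .data$rc_sd,
                                          ymax = .data$rc_mean + .data$rc_sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(y = "recovery coefficient", x = NULL, colour = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a misregistration experiment
#'
#' Normalized recovery coefficient versus shift (1 at zero shift by
#' construction), per method.
#'
#' @param object a `pvc_shift_experiment`.
#' @param regions optional subset of regions to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pvc_shift_experiment <- function(object, regions = NULL, ...) {
  df <- dplyr::filter(object, !is.na(.data$rc_norm))
  if (!is.null(regions)) df <- dplyr::filter(df, .data$region %in% regions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$rc_norm,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$region) +
    ggplot2::labs(x = sprintf("mask shift along %s (mm)", attr(object, "axis")),
                  y = "normalized recovery coefficient", colour = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
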