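#' Voxelize a ground-truth network into an image stack
#'
#' Lacunae are drawn as filled ellipsoids and canaliculi as tubes of radius
#' `params$canaliculus_radius_um` around the edge paths. Both use a
#' supersampled inside test (3 x 3 x 3 subsamples per voxel, i.e. 3x
#' supersampling per axis before downsampling), so the sub-voxel tube radius
#' produces partial-volume intensities. Voxel values are the maximum coverage
#' fraction over all structures, on a 0..1 scale; background is 0.
#'
#' @param truth an `lcn_truth` from [generate_ground_truth()].
#' @param params a [generator_params()]; defaults to the truth's own.
#' @param allow_large permit more than 256^3 voxels (memory guard).
#' @return An [image_stack()].
#' @export
rasterize <- function(truth, params = truth$params, allow_large = FALSE) {
  L <- params$domain_size_um
  spacing <- params$voxel_spacing_um
  dims <- pmax(1L, as.integer(ceiling(L / spacing - 1e-9)))
  if (prod(dims) > 256^3 && !allow_large)
    stop("rasterization would need ", paste(dims, collapse = " x "),
         " voxels (> 256^3); pass allow_large = TRUE to override")
  img <- numeric(prod(dims))
  n_lac <- nrow(truth$lacunae)
  if (n_lac > 0) {
    semi <- cbind(truth$lacunae$a_um, truth$lacunae$b_um, truth$lacunae$c_um)
    img <- cpp_raster_ellipsoids(truth$lacuna_centers, semi,
                                 truth$lacuna_rotations, dims, spacing, img)
  }
  if (length(truth$graph$paths))
    img <- cpp_raster_tubes(truth$graph$paths, params$canaliculus_radius_um,
                            dims, spacing, img)
  dim(img) <- dims
  image_stack(img, spacing)
}

#' Apply confocal-like degradation to a phantom image
#'
#' In order: anisotropic Gaussian blur (`psf_sigma_um`), an additive linear
#' background ramp along x (`background_gradient`, intensity per um), and
#' additive Gaussian noise (`noise_sd`). The noise stream is seeded from
#' `params$seed`, so the same parameters give a bit-identical result.
#'
#' @param image an [image_stack()].
#' @param params a [generator_params()].
#' @return A degraded [image_stack()] on the same grid.
#' @export
degrade <- function(image, params = generator_params()) {
  stopifnot(inherits(image, "lcn_stack"))
  if (any(params$psf_sigma_um < 0) || params$noise_sd < 0)
    stop("psf_sigma_um and noise_sd must be >= 0")
  dims <- dim(image$data)
  out <- image$data
  sig_vox <- params$psf_sigma_um / image$spacing_um
  if (any(sig_vox > 0)) {
    out <- cpp_gauss_blur3d(as.numeric(out), as.integer(dims), sig_vox)
    dim(out) <- dims
  }
  if (params$background_gradient != 0) {
    x <- (seq_len(dims[1]) - 0.5) * image$spacing_um[1]
    out <- out + array(params$background_gradient * x, dim = dims)
  }
  if (params$noise_sd > 0) {
    set.seed(offset_seed(params$seed, 101))
    out <- out + array(rnorm(prod(dims), 0, params$noise_sd), dim = dims)
  }
  image_stack(out, image$spacing_um, image$origin_um)
}

#' Generate a cohort of phantoms emulating a two-strain, two-limb study
#'
#' For each preset (mouse strain) and animal, density targets are jittered by
#' a small multiplicative animal-level factor (lognormal,
#' `animal_jitter_cv` coefficient of variation), and both limbs of the animal
#' share those animal-level targets while using different seeds. This
#' reproduces the study structure in which between-animal variability is much
#' smaller than the within-sample (subvolume-to-subvolume) variability.
#'
#' @param presets list of [strain_preset()]s.
#' @param n_per_group animals per strain (each contributes two limbs).
#' @param seed master seed; animal jitter and per-limb seeds derive from it.
#' @param base_params template [generator_params()].
#' @param rasterize_stacks if `TRUE`, also rasterize + degrade each phantom
#'   (slow); otherwise only ground truths are produced.
#' @param animal_jitter_cv coefficient of variation of the animal-level
#'   multiplicative jitter on the density targets.
#' @return A list of samples, each
#'   `list(truth, image, strain, animal, limb, seed)`.
#' @export
generate_cohort <- function(presets = list(strain_preset("balbc_like"),
                                           strain_preset("c57_like")),
                            n_per_group = 5, seed = 1L,
                            base_params = generator_params(),
                            rasterize_stacks = FALSE,
                            animal_jitter_cv = 0.04) {
  stopifnot(n_per_group >= 1)
  set.seed(seed %% 2147483647)
  samples <- list()
  for (preset in presets) {
    for (animal in seq_len(n_per_group)) {
      jit_can <- exp(rnorm(1, 0, animal_jitter_cv))
      jit_node <- exp(rnorm(1, 0, animal_jitter_cv))
      limb_seeds <- sample.int(2147483646L, 2)
      for (li in 1:2) {
        p <- base_params
        p$target_can_density <- preset$target_can_density * jit_can
        p$target_node_density <- preset$target_node_density * jit_node
        p$degree_tail_beta <- preset$degree_tail_beta
        p$lacuna_mean_volume_um3 <- preset$lacuna_mean_volume_um3
        p$unordered_fraction <- preset$unordered_fraction
        p$seed <- limb_seeds[li]
        truth <- generate_ground_truth(p)
        img <- if (rasterize_stacks) degrade(rasterize(truth, p), p) else NULL
        samples[[length(samples) + 1L]] <-
          list(truth = truth, image = img, strain = preset$name,
               animal = animal, limb = c("left", "right")[li],
               seed = limb_seeds[li])
      }
    }
  }
  samples
}

#' Labels of a generated cohort as a data.frame
#'
#' @param cohort result of [generate_cohort()].
#' @return data.frame with `strain`, `animal`, `limb`, `seed` and the realized
#'   overall Can.Dn / Nd.Nr of each sample's ground truth.
#' @export
cohort_labels <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(strain = s$strain, animal = s$animal, limb = s$limb,
               seed = s$seed,
               can_dn = s$truth$realized$overall$can_dn,
               nd_nr = s$truth$realized$overall$nd_nr)))
}

#' Generate a co-registered qBEI gray-level phantom
#'
#' Produces an 8-bit backscattered-electron-like gray image over the xy
#' extent of a ground truth. If the truth carries an interface plane, pixels
#' on the low side take the gray level of `low_ca` and pixels on the high
#' side that of `high_ca` (per the supplied calibration), so the calcium
#' interface coincides by construction with the network disruption. Without
#' an interface the whole map sits at `low_ca`.
#'
#' @param truth an `lcn_truth`.
#' @param low_ca,high_ca calcium content (wt% Ca) of the two phases;
#'   `0 <= low_ca < high_ca`.
#' @param curve a [build_calibration()] curve.
#' @param noise_gl_sd Gaussian gray-level noise SD (added before rounding).
#' @param pixel_spacing_um xy pixel size; defaults to the truth's voxel size.
#' @return list with `gl` (integer matrix 0..255), `ca_true` (matrix, wt%Ca),
#'   `curve`, `pixel_spacing_um`.
#' @export
generate_qbei_phantom <- function(truth, low_ca, high_ca,
                                  curve = build_calibration(),
                                  noise_gl_sd = 0,
                                  pixel_spacing_um =
                                    truth$params$voxel_spacing_um[1:2]) {
  if (!(low_ca >= 0 && low_ca < high_ca))
    stop("need 0 <= low_ca < high_ca")
  L <- truth$params$domain_size_um
  dims <- pmax(1L, as.integer(ceiling(L[1:2] / pixel_spacing_um - 1e-9)))
  gl_low <- gray_for_ca(curve, low_ca)
  gl_high <- gray_for_ca(curve, high_ca)
  ca <- matrix(low_ca, dims[1], dims[2])
  gl <- matrix(gl_low, dims[1], dims[2])
  ip <- truth$interface_plane
  if (!is.null(ip) && ip$axis %in% c("x", "y")) {
    ax <- match(ip$axis, c("x", "y"))
    coord <- (seq_len(dims[ax]) - 0.5) * pixel_spacing_um[ax]
    hi <- coord >= ip$position_um
    if (ax == 1) {
      ca[hi, ] <- high_ca
      gl[hi, ] <- gl_high
    } else {
      ca[, hi] <- high_ca
      gl[, hi] <- gl_high
    }
  }
  if (noise_gl_sd > 0) {
    set.seed(offset_seed(truth$seed, 202))
    gl <- gl + matrix(rnorm(length(gl), 0, noise_gl_sd), dims[1], dims[2])
  }
  gl <- matrix(as.integer(pmin(255, pmax(0, round(gl)))), dims[1], dims[2])
  list(gl = gl, ca_true = ca, curve = curve,
       pixel_spacing_um = pixel_spacing_um)
}
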