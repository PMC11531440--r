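#' 2D region mask (ordered / unordered network)
#'
#' @param labels integer matrix aligned with the stack's xy frame; 0 =
#'   outside the ROI, 1 = ordered, 2 = unordered.
#' @param pixel_spacing_um length-2 pixel size (um).
#' @param provenance free-text tag (e.g. `"manual"` or `"phantom-truth"`).
#' @return list of class `region_mask2d`.
#' @export
region_mask2d <- function(labels, pixel_spacing_um, provenance = "manual") {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 0:2))
    stop("labels must be 0 (outside), 1 (ordered) or 2 (unordered)")
  structure(list(labels = labels,
                 pixel_spacing_um = as.numeric(pixel_spacing_um),
                 provenance = provenance), class = "region_mask2d")
}

#' Intensity projection of a skeleton along z
#'
#' Collapses the skeleton to a single xy image, either counting skeleton
#' voxels per pixel column (`"count"`) or taking their maximum (`"max"`).
#' This projected image is the basis for the manual separation of ordered
#' (comb-like) from unordered (whirl-like) network regions.
#'
#' @param skel an `lcn_skel` from [skeletonize_mask()], or a logical 3D array.
#' @param mode `"count"` or `"max"`.
#' @return numeric matrix (nx x ny).
#' @export
project_skeleton_z <- function(skel, mode = c("count", "max")) {
  mode <- match.arg(mode)
  arr <- if (inherits(skel, "lcn_skel")) skel$skel else skel
  stopifnot(length(dim(arr)) == 3)
  proj <- apply(arr, c(1, 2), if (mode == "count") sum else max)
  proj * 1.0
}

#' Orientation coherence of a projected skeleton
#'
#' Structure-tensor anisotropy of the z-projection: per pixel,
#' `(l1 - l2) / (l1 + l2)` of the Gaussian-windowed gradient outer product.
#' High values mean locally parallel (comb-like) texture; low values mean
#' isotropic (whirl-like) texture. A drafting aid for region masks - it is
#' not a replacement for the manual segmentation.
#'
#' @param proj numeric matrix (e.g. from [project_skeleton_z()]).
#' @param window_sigma_px Gaussian window SD in pixels.
#' @return matrix of coherence values in `[0, 1]`.
#' @export
orientation_coherence <- function(proj, window_sigma_px = 8) {
  nx <- nrow(proj); ny <- ncol(proj)
  gx <- (rbind(proj[-1, ], proj[nx, ]) - rbind(proj[1, ], proj[-nx, ])) / 2
  gy <- (cbind(proj[, -1], proj[, ny]) - cbind(proj[, 1], proj[, -ny])) / 2
  blur2 <- function(m) {
    a <- array(m, c(nx, ny, 1))
    out <- cpp_gauss_blur3d(as.numeric(a), c(nx, ny, 1L),
                            c(window_sigma_px, window_sigma_px, 0))
    matrix(out, nx, ny)
  }
  jxx <- blur2(gx * gx); jyy <- blur2(gy * gy); jxy <- blur2(gx * gy)
  tr <- jxx + jyy
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  out <- ifelse(tr > 1e-12, disc / tr, 0)
  pmin(pmax(out, 0), 1)
}

#' Region-wise subvolume statistics and area fractions
#'
#' Assigns each valid subvolume cell the majority region label of its xy
#' pixel footprint (the 2D mask is extruded along z; ties go to "unordered",
#' the sparser class) and returns per-region value lists for Can.Dn, Nd.Nr
#' and Nd.Dg together with region area fractions (shares of in-ROI pixels).
#'
#' @param map a `subvolume_map` from [compute_subvolume_maps()].
#' @param mask a [region_mask2d()] covering the map's xy extent.
#' @return list of class `region_stats`: `area_fraction` (named, sums to 1
#'   over ordered/unordered), `per_region` (list of data.frames with the cell
#'   values), `n_cells` (named).
#' @export
region_statistics <- function(map, mask) {
  stopifnot(inherits(map, "subvolume_map"), inherits(mask, "region_mask2d"))
  h <- attr(map, "cell_edge_um")
  dom <- attr(map, "domain_size_um")
  sp <- mask$pixel_spacing_um
  dims <- dim(mask$labels)
  if (any(dims * sp < dom[1:2] - h))
    stop("region mask does not cover the map's xy extent")

  px <- (seq_len(dims[1]) - 0.5) * sp[1]
  py <- (seq_len(dims[2]) - 0.5) * sp[2]
  lab <- mask$labels
  inroi <- lab > 0
  area <- c(ordered = sum(lab == 1L), unordered = sum(lab == 2L))
  if (sum(area) == 0) stop("region mask has no in-ROI pixels")
  area_fraction <- area / sum(area)

  cells <- map[map$valid, , drop = FALSE]
  region <- character(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    xi <- which(px >= (cells$ix[r] - 1) * h & px < cells$ix[r] * h)
    yi <- which(py >= (cells$iy[r] - 1) * h & py < cells$iy[r] * h)
    sub <- lab[xi, yi]
    n_ord <- sum(sub == 1L); n_un <- sum(sub == 2L)
    region[r] <- if (n_ord + n_un == 0) "outside"
    else if (n_ord > n_un) "ordered" else "unordered"
  }
  per_region <- lapply(c(ordered = "ordered", unordered = "unordered"),
                       function(rg) cells[region == rg,
                                          c("ix", "iy", "iz", "can_dn",
                                            "nd_nr", "nd_dg")])
  structure(list(area_fraction = area_fraction, per_region = per_region,
                 n_cells = vapply(per_region, nrow, integer(1))),
            class = "region_stats")
}
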