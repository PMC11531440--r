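#' Parameters of the synthetic LCN phantom generator
#'
#' Bundles every knob of the ground-truth generator. Defaults emulate the
#' canalicular architecture of adult mouse cortical bone as measured by
#' confocal imaging of stained tibial cross-sections: canalicular density
#' around 0.21 um/um^3, about 0.05 network nodes per um^3 dominated by degree
#' three with an exponential tail, rod-like lacunae of roughly 350 um^3 with
#' on the order of 50 emanating canaliculi, and an unordered (woven-bone-like)
#' band occupying close to 30% of the volume.
#'
#' @param domain_size_um length-3, physical size of the simulated block (um).
#' @param voxel_spacing_um length-3, voxel spacing for rasterization (um).
#' @param lacuna_number_density lacunae per um^3.
#' @param lacuna_mean_volume_um3 mean lacunar volume (um^3) at unit size
#'   factor; individual lacunae scale linearly by a uniform factor in
#'   \[0.7, 1.3\].
#' @param lacuna_axis_ratios length-3 decreasing, ellipsoid semi-axis ratios
#'   a:b:c. The default (4 : 2.2 : 1.5) gives stretch 1 - c/a = 0.62 and
#'   oblateness -0.44 (rod-like).
#' @param target_node_density junctions per um^3 (lacunae are additional).
#' @param target_can_density canalicular length per volume (um/um^3).
#' @param degree_tail_beta decay constant of the junction degree tail:
#'   P(degree >= x) = exp(-beta (x - 3)).
#' @param canaliculus_radius_um tube radius (um); 0.15 um matches the ~300 nm
#'   canalicular diameter.
#' @param area_per_canaliculus_um2 lacunar surface area per primary
#'   canaliculus; lacunar degree = round(area / this).
#' @param unordered_fraction volume fraction of the unordered (sparser,
#'   isotropic) region; the region is a slab `y < unordered_fraction * Ly`.
#' @param ordered_alignment_axis unit 3-vector; edges in the ordered region
#'   align with it to within about 20 degrees.
#' @param tortuosity_factor target edge arc length / chord length (>= 1).
#' @param psf_sigma_um length-3 Gaussian blur sigma of the simulated optics.
#' @param noise_sd additive Gaussian noise SD (intensity units; images are
#'   generated on a 0..1 scale).
#' @param background_gradient linear intensity ramp along x (intensity/um).
#' @param interface_plane `NULL`, or `list(axis = "x", position_um = ...)`
#'   describing a plane no canaliculus may cross (a mineral interface with a
#'   network disruption).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(domain_size_um = c(50, 50, 50),
                             voxel_spacing_um = c(0.379, 0.379, 0.340),
                             lacuna_number_density = 3e-5,
                             lacuna_mean_volume_um3 = 350,
                             lacuna_axis_ratios = c(4, 2.2, 1.5),
                             target_node_density = 0.05,
                             target_can_density = 0.21,
                             degree_tail_beta = 1.2,
                             canaliculus_radius_um = 0.15,
                             area_per_canaliculus_um2 = 5.75,
                             unordered_fraction = 0.3,
                             ordered_alignment_axis = c(1, 0, 0),
                             tortuosity_factor = 1.1,
                             psf_sigma_um = c(0.2, 0.2, 0.35),
                             noise_sd = 0.02,
                             background_gradient = 5e-4,
                             interface_plane = NULL,
                             junction_min_separation_um = 1.2,
                             edge_clearance_um = 1.2,
                             seed = 1L) {
  p <- list(domain_size_um = as.numeric(domain_size_um),
            voxel_spacing_um = as.numeric(voxel_spacing_um),
            lacuna_number_density = lacuna_number_density,
            lacuna_mean_volume_um3 = lacuna_mean_volume_um3,
            lacuna_axis_ratios = as.numeric(lacuna_axis_ratios),
            target_node_density = target_node_density,
            target_can_density = target_can_density,
            degree_tail_beta = degree_tail_beta,
            canaliculus_radius_um = canaliculus_radius_um,
            area_per_canaliculus_um2 = area_per_canaliculus_um2,
            unordered_fraction = unordered_fraction,
            ordered_alignment_axis = as.numeric(ordered_alignment_axis),
            tortuosity_factor = tortuosity_factor,
            psf_sigma_um = as.numeric(psf_sigma_um),
            noise_sd = noise_sd,
            background_gradient = background_gradient,
            interface_plane = interface_plane,
            junction_min_separation_um = junction_min_separation_um,
            edge_clearance_um = edge_clearance_um,
            seed = as.integer(seed))
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  stopifnot(length(p$domain_size_um) == 3, all(p$domain_size_um > 0))
  stopifnot(length(p$voxel_spacing_um) == 3, all(p$voxel_spacing_um > 0))
  if (p$lacuna_number_density < 0 || p$target_node_density < 0 ||
      p$target_can_density < 0)
    stop("densities must be >= 0")
  if (!(p$degree_tail_beta > 0)) stop("degree_tail_beta must be > 0")
  if (p$unordered_fraction < 0 || p$unordered_fraction > 1)
    stop("unordered_fraction must lie in [0, 1]")
  if (p$tortuosity_factor < 1) stop("tortuosity_factor must be >= 1")
  if (any(diff(p$lacuna_axis_ratios) > 0))
    stop("lacuna_axis_ratios must be non-increasing (a >= b >= c)")
  if (!is.null(p$interface_plane)) {
    if (!is.list(p$interface_plane) ||
        !all(c("axis", "position_um") %in% names(p$interface_plane)) ||
        !p$interface_plane$axis %in% c("x", "y", "z"))
      stop("interface_plane must be list(axis = 'x'|'y'|'z', position_um = ...)")
  }
  invisible(p)
}

#' Mouse-strain presets for the generator
#'
#' Two presets mirroring the study conditions of a strain comparison:
#' `"balbc_like"` (Can.Dn 0.21 um/um^3, Nd.Nr 0.05 um^-3) and `"c57_like"`
#' (Can.Dn 0.23, Nd.Nr 0.059, i.e. strictly denser, with slightly more lacunar
#' canaliculi). The degree-tail exponent beta is close to 1 for both.
#'
#' @param name `"balbc_like"` or `"c57_like"`.
#' @return A list of class `strain_preset` with fields `name`,
#'   `target_can_density`, `target_node_density`, `degree_tail_beta`,
#'   `lacuna_mean_volume_um3`, `unordered_fraction`.
#' @export
strain_preset <- function(name = c("balbc_like", "c57_like")) {
  name <- match.arg(name)
  p <- switch(name,
    balbc_like = list(name = "balbc_like", target_can_density = 0.21,
                      target_node_density = 0.050, degree_tail_beta = 1.2,
                      lacuna_mean_volume_um3 = 350, unordered_fraction = 0.28),
    c57_like = list(name = "c57_like", target_can_density = 0.23,
                    target_node_density = 0.059, degree_tail_beta = 1.15,
                    lacuna_mean_volume_um3 = 350, unordered_fraction = 0.30))
  structure(p, class = "strain_preset")
}

#' Approximate surface area of an ellipsoid
#'
#' Thomsen's approximation (p = 1.6075), accurate to ~1% for all shapes.
#'
#' @param a,b,c semi-axes (um).
#' @return Surface area (um^2), vectorized over the inputs.
#' @export
ellipsoid_surface_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Mean edge length implied by density targets
#'
#' With node density `nd_nr` (nodes/um^3), mean node degree `nd_dg` and
#' canalicular density `can_dn` (um/um^3), the expected edge count per volume
#' is `nd_nr * nd_dg / 2`, so the implied mean edge length is
#' `can_dn / (nd_nr * nd_dg / 2)`.
#'
#' @param can_dn canalicular density (um/um^3).
#' @param nd_nr node density (um^-3).
#' @param nd_dg mean node degree.
#' @return Mean edge length in um.
#' @export
implied_mean_edge_length <- function(can_dn, nd_nr, nd_dg) {
  can_dn / (nd_nr * nd_dg / 2)
}

# mean junction degree for the discretized exponential tail
mean_degree_for_beta <- function(beta) 3 + 1 / (expm1(beta))

## ---- small geometry helpers -------------------------------------------------

fibonacci_dirs <- function(n) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  matrix(c(c0 + a[1]^2 * C, a[1] * a[2] * C + a[3] * s0, a[1] * a[3] * C - a[2] * s0,
           a[1] * a[2] * C - a[3] * s0, c0 + a[2]^2 * C, a[2] * a[3] * C + a[1] * s0,
           a[1] * a[3] * C + a[2] * s0, a[2] * a[3] * C - a[1] * s0, c0 + a[3]^2 * C),
         3, 3)
}

# rotation taking e1 to the unit vector v
rot_align_x <- function(v) {
  v <- v / sqrt(sum(v^2))
  e1 <- c(1, 0, 0)
  c0 <- sum(e1 * v)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  ax <- c(e1[2] * v[3] - e1[3] * v[2], e1[3] * v[1] - e1[1] * v[3],
          e1[1] * v[2] - e1[2] * v[1])
  rot_axis_angle(ax, acos(c0))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: Haar-ish and good enough for phantoms
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

offset_seed <- function(seed, k) (as.numeric(seed) + k) %% 2147483647

## ---- lacuna population ------------------------------------------------------

#' Sample a population of ellipsoidal lacunae (shape only)
#'
#' Draws lacunae with the generator's shape model: fixed axis ratios, linear
#' size factor uniform in \[0.7, 1.3\], volume from the ellipsoid formula,
#' surface area from [ellipsoid_surface_area()], and lacunar degree set to
#' `round(area / area_per_canaliculus_um2)` (constant area per canaliculus).
#'
#' @param n number of lacunae.
#' @param params a [generator_params()].
#' @return data.frame with semi-axes `a_um >= b_um >= c_um`, `volume_um3`,
#'   `area_um2`, `degree`, `stretch` (1 - c/a) and `oblateness`
#'   (2 (b - c) / (a - c) - 1).
#' @export
sample_lacuna_shapes <- function(n, params = generator_params()) {
  if (n == 0)
    return(data.frame(id = integer(), size_factor = numeric(), a_um = numeric(),
                      b_um = numeric(), c_um = numeric(), volume_um3 = numeric(),
                      area_um2 = numeric(), degree = integer(),
                      stretch = numeric(), oblateness = numeric()))
  r <- params$lacuna_axis_ratios
  s <- (3 * params$lacuna_mean_volume_um3 / (4 * pi * prod(r)))^(1 / 3)
  u <- runif(n, 0.7, 1.3)
  a <- s * r[1] * u; b <- s * r[2] * u; c <- s * r[3] * u
  vol <- 4 / 3 * pi * a * b * c
  area <- ellipsoid_surface_area(a, b, c)
  data.frame(id = seq_len(n), size_factor = u, a_um = a, b_um = b, c_um = c,
             volume_um3 = vol, area_um2 = area,
             degree = as.integer(round(area / params$area_per_canaliculus_um2)),
             stretch = 1 - c / a,
             oblateness = ifelse(a - c < 1e-6, 0, 2 * (b - c) / (a - c) - 1))
}

## ---- region helpers ---------------------------------------------------------

# unordered region is the slab y < unordered_fraction * Ly
region_is_unordered <- function(pts, params) {
  pts[, 2] < params$unordered_fraction * params$domain_size_um[2]
}

#' Per-voxel region labels of a ground truth (1 = ordered, 2 = unordered)
#'
#' @param truth an `lcn_truth` from [generate_ground_truth()].
#' @param spacing_um voxel spacing; defaults to the generator's.
#' @return 3D integer array.
#' @export
region_label_field <- function(truth, spacing_um = truth$params$voxel_spacing_um) {
  L <- truth$params$domain_size_um
  dims <- pmax(1L, as.integer(ceiling(L / spacing_um - 1e-9)))
  y <- (seq_len(dims[2]) - 0.5) * spacing_um[2]
  lab <- ifelse(y < truth$params$unordered_fraction * L[2], 2L, 1L)
  array(rep(rep(lab, each = dims[1]), dims[3]), dim = dims)
}

#' 2D region mask of a ground truth, for region-wise statistics
#'
#' The unordered band of the phantom is constant along z, so its z-projection
#' is the exact 2D mask (1 = ordered, 2 = unordered).
#'
#' @inheritParams region_label_field
#' @return A list of class `region_mask2d` with `labels` (matrix, 0 = outside,
#'   1 = ordered, 2 = unordered), `pixel_spacing_um` and `provenance`.
#' @export
truth_region_mask <- function(truth, spacing_um = truth$params$voxel_spacing_um[1:2]) {
  L <- truth$params$domain_size_um
  dims <- pmax(1L, as.integer(ceiling(L[1:2] / spacing_um - 1e-9)))
  y <- (seq_len(dims[2]) - 0.5) * spacing_um[2]
  lab <- ifelse(y < truth$params$unordered_fraction * L[2], 2L, 1L)
  labels <- matrix(rep(lab, each = dims[1]), dims[1], dims[2])
  region_mask2d(labels, spacing_um, provenance = "phantom-truth")
}

## ---- tortuosity -------------------------------------------------------------

# Lookup of the half-wave bump amplitude (fraction of the chord) realizing
# a given discrete arc/chord ratio for an npts-point polyline.
tortuosity_alpha <- function(npts, tf) {
  if (tf <= 1 || npts < 5) return(0)
  s <- seq(0, 1, length.out = npts)
  alphas <- seq(0, 0.6, by = 0.01)
  ratios <- vapply(alphas, function(a) {
    pts <- cbind(s, a * sin(pi * s))
    sum(sqrt(rowSums(diff(pts)^2)))
  }, numeric(1))
  if (tf >= max(ratios)) return(max(alphas))
  stats::approx(ratios, alphas, xout = tf, ties = "ordered")$y
}

# path from a to b with arc/chord ~ tf; u_perp must be unit, perpendicular to b-a
tortuous_path <- function(a, b, tf, u_perp, alpha_cache) {
  chord <- sqrt(sum((b - a)^2))
  npts <- max(2L, as.integer(round(chord / 0.5)) + 1L)
  if (tf > 1) npts <- max(5L, npts)
  key <- as.character(npts)
  if (is.null(alpha_cache[[key]]))
    alpha_cache[[key]] <- tortuosity_alpha(npts, tf)
  alpha <- alpha_cache[[key]]
  s <- seq(0, 1, length.out = npts)
  base <- outer(1 - s, a) + outer(s, b)
  if (alpha > 0)
    base <- base + outer(alpha * chord * sin(pi * s), u_perp)
  base
}

## ---- ground truth -----------------------------------------------------------

#' Generate a ground-truthed synthetic LCN
#'
#' Builds the true spatial network of a phantom: ellipsoidal lacunae placed by
#' a hard-core point process, junctions with degrees drawn from the discretized
#' exponential-tail distribution P(k) = exp(-beta (k-3)) - exp(-beta (k-2)),
#' canaliculi laid down by proximity-based stub matching with a target mean
#' edge length chosen so the realized canalicular density and node density hit
#' their targets, edge alignment inside the ordered region, tortuous edge
#' paths, and (optionally) a forbidden interface plane that no canaliculus
#' crosses. All randomness flows from `params$seed`; the draw order is
#' lacunae, junctions, degrees, matching order, dangling directions, edge
#' perturbations.
#'
#' @param params a [generator_params()].
#' @return An object of class `lcn_truth`: list with `graph` ([lcn_graph()]),
#'   `lacunae` (truth table incl. rotations), `region`, `interface_plane`,
#'   `realized` (overall and per-region Can.Dn / Nd.Nr / mean degrees),
#'   `params`, `seed`, `metadata` (implied mean edge length, match rate, ...).
#' @export
generate_ground_truth <- function(params = generator_params()) {
  validate_generator_params(params)
  set.seed(params$seed %% 2147483647)
  L <- params$domain_size_um
  V <- prod(L)
  spacing <- params$voxel_spacing_um

  ## feasibility of the density targets
  mean_deg <- mean_degree_for_beta(params$degree_tail_beta)
  implied <- NA_real_
  if (params$target_node_density > 0 && params$target_can_density > 0) {
    implied <- implied_mean_edge_length(params$target_can_density,
                                        params$target_node_density, mean_deg)
    if (implied < 2 * max(spacing))
      stop("infeasible target combination: implied mean edge length ",
           signif(implied, 3), " um is below 2 voxels (",
           signif(2 * max(spacing), 3), " um)")
  }

  ## 1. lacunae -----------------------------------------------------------
  n_lac <- rpois(1, params$lacuna_number_density * V)
  shapes <- sample_lacuna_shapes(n_lac, params)
  centers <- matrix(numeric(), 0, 3)
  rots <- list()
  if (n_lac > 0) {
    min_sep <- 2 * mean(shapes$a_um)
    if (any(2 * shapes$a_um >= min(L)))
      stop("lacunae do not fit in the domain")
    place_all <- function() {
      placed <- 0L
      attempts <- 0L
      centers <- matrix(NA_real_, n_lac, 3)
      while (placed < n_lac && attempts < 500L * n_lac) {
        attempts <- attempts + 1L
        i <- placed + 1L
        m <- shapes$a_um[i]
        cand <- runif(3, m, L - m)
        ok <- placed == 0L ||
          all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 3, byrow = TRUE))^2)) >=
                min_sep)
        if (ok) {
          centers[i, ] <- cand
          placed <- placed + 1L
        }
      }
      if (placed < n_lac) NULL else centers
    }
    centers <- NULL
    for (restart in 1:20) { # sequential placement can dead-end: redraw
      centers <- place_all()
      if (!is.null(centers)) break
    }
    if (is.null(centers))
      stop("could not place ", n_lac, " lacunae with hard-core separation ",
           signif(min_sep, 3), " um; lower lacuna_number_density")
    unord <- region_is_unordered(centers, params)
    axis_u <- params$ordered_alignment_axis /
      sqrt(sum(params$ordered_alignment_axis^2))
    rots <- lapply(seq_len(n_lac), function(i) {
      if (unord[i]) return(random_rotation())
      tilt <- rot_axis_angle(rnorm(3), runif(1, 0, 20 * pi / 180))
      roll <- rot_axis_angle(c(1, 0, 0), runif(1, 0, 2 * pi))
      tilt %*% rot_align_x(axis_u) %*% roll
    })
  }

  ## 2. junctions ---------------------------------------------------------
  n_j <- rpois(1, params$target_node_density * V)
  jpos <- matrix(numeric(), 0, 3)
  if (n_j > 0) {
    unord_weight <- 0.65 # relative junction density in the unordered region
    acc <- matrix(numeric(), 0, 3)
    rounds <- 0L
    infl_semi <- if (n_lac > 0)
      cbind(shapes$a_um, shapes$b_um, shapes$c_um) + 1.0 else NULL
    while (nrow(acc) < n_j && rounds < 80L) {
      rounds <- rounds + 1L
      batch <- max(1000L, 3L * (n_j - nrow(acc)))
      pts <- cbind(runif(batch, 0, L[1]), runif(batch, 0, L[2]),
                   runif(batch, 0, L[3]))
      w <- ifelse(region_is_unordered(pts, params), unord_weight, 1)
      pts <- pts[runif(batch) < w, , drop = FALSE]
      if (n_lac > 0 && nrow(pts))
        pts <- pts[!points_in_ellipsoids(pts, centers, infl_semi, rots), ,
                   drop = FALSE]
      all_pts <- rbind(acc, pts)
      # hard core: junctions closer than the imaging resolution are not
      # observably distinct, so the resolved network never contains them
      keep <- cpp_hardcore_keep(all_pts, params$junction_min_separation_um, L)
      acc <- all_pts[keep, , drop = FALSE]
    }
    if (nrow(acc) < n_j)
      stop("could not place ", n_j, " junctions; targets too dense")
    jpos <- acc[seq_len(n_j), , drop = FALSE]
  }

  ## 3. degrees -----------------------------------------------------------
  jdeg <- if (n_j > 0)
    3L + rgeom(n_j, 1 - exp(-params$degree_tail_beta)) else integer()

  ## 4. stub sites --------------------------------------------------------
  site_pos <- matrix(numeric(), 0, 3)
  site_node <- integer()
  site_ell <- integer()
  site_norm <- matrix(numeric(), 0, 3)
  if (n_j > 0) {
    site_pos <- jpos[rep(seq_len(n_j), jdeg), , drop = FALSE]
    site_node <- rep(seq_len(n_j), jdeg) - 1L
    site_ell <- rep(0L, nrow(site_pos))
    site_norm <- matrix(0, nrow(site_pos), 3)
  }
  if (n_lac > 0) {
    for (i in seq_len(n_lac)) {
      k <- shapes$degree[i]
      if (k <= 0) next
      dirs <- fibonacci_dirs(k)
      semi <- c(shapes$a_um[i], shapes$b_um[i], shapes$c_um[i])
      surf <- t(rots[[i]] %*% t(dirs * matrix(semi, k, 3, byrow = TRUE))) +
        matrix(centers[i, ], k, 3, byrow = TRUE)
      nrm <- dirs / matrix(semi, k, 3, byrow = TRUE)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      nrm <- t(rots[[i]] %*% t(nrm))
      keep <- surf[, 1] > 0.2 & surf[, 1] < L[1] - 0.2 &
        surf[, 2] > 0.2 & surf[, 2] < L[2] - 0.2 &
        surf[, 3] > 0.2 & surf[, 3] < L[3] - 0.2
      surf <- surf[keep, , drop = FALSE]
      nrm <- nrm[keep, , drop = FALSE]
      site_pos <- rbind(site_pos, surf)
      site_node <- c(site_node, rep(n_j + i - 1L, nrow(surf)))
      site_ell <- c(site_ell, rep(i, nrow(surf)))
      site_norm <- rbind(site_norm, nrm)
    }
  }
  m <- nrow(site_pos)

  ## 5. matching ----------------------------------------------------------
  axis_u <- params$ordered_alignment_axis /
    sqrt(sum(params$ordered_alignment_axis^2))
  iface_axis <- -1L
  iface_pos <- 0
  if (!is.null(params$interface_plane)) {
    iface_axis <- match(params$interface_plane$axis, c("x", "y", "z")) - 1L
    iface_pos <- params$interface_plane$position_um
  }

  edges_nodes <- matrix(integer(), 0, 2)
  edge_paths <- list()
  end_pos <- matrix(numeric(), 0, 3)
  match_rate <- NA_real_
  d_star <- NA_real_
  if (m > 0 && params$target_can_density > 0) {
    d_star0 <- params$target_can_density * V /
      (params$tortuosity_factor * m / 2)
    if (d_star0 < 2 * max(spacing))
      stop("infeasible target combination: stub-implied edge length ",
           signif(d_star0, 3), " um is below 2 voxels")
    aligned <- !region_is_unordered(site_pos, params)
    ord <- sample.int(m) - 1L
    rnd <- matrix(rnorm(3 * m), m, 3)
    rnd <- rnd / sqrt(rowSums(rnd^2))
    is_lac_site <- site_ell > 0L
    rnd[is_lac_site, ] <- site_norm[is_lac_site, , drop = FALSE]
    ell_semi_infl <- if (n_lac > 0)
      cbind(shapes$a_um, shapes$b_um, shapes$c_um) + 0.5
    else matrix(numeric(), 0, 3)
    # calibrate d_star so the realized total chord length hits the target:
    # unmatched stubs turn into dangling branches, which inflates the edge
    # count beyond m/2, so the naive d_star overshoots. The matcher is
    # deterministic given (order, rand_dirs), so re-running it with a
    # rescaled d_star is a clean fixed-point iteration.
    L_target <- params$target_can_density * V / params$tortuosity_factor
    d_star <- d_star0
    # resolvability floor: no edge chord below ~4 voxels, or junction pairs
    # fuse under the imaging blur and their edges cannot be recovered
    floor_d <- max(2 * max(spacing), params$junction_min_separation_um)
    for (it in 1:8) {
      r_max <- max(3.5 * d_star, 3)
      d_min <- min(params$junction_min_separation_um, 0.6 * d_star)
      clearance <- params$edge_clearance_um
      res <- cpp_match_stubs(site_pos, site_node, aligned, site_ell,
                             axis_u, cos(20 * pi / 180),
                             d_star, r_max, d_min, clearance,
                             centers, ell_semi_infl,
                             rots, iface_axis, iface_pos, ord, rnd, L)
      chord_len <- function(a, b) sqrt(rowSums((b - a)^2))
      tot <- 0
      if (nrow(res$edges))
        tot <- tot + sum(chord_len(site_pos[res$edges[, 1] + 1L, , drop = FALSE],
                                   site_pos[res$edges[, 2] + 1L, , drop = FALSE]))
      if (length(res$dangling_site))
        tot <- tot + sum(chord_len(site_pos[res$dangling_site + 1L, ,
                                            drop = FALSE],
                                   res$dangling_end))
      if (tot <= 0) break
      err <- tot / L_target
      if (abs(err - 1) < 0.03) break
      # dampened multiplicative update: chord totals respond sublinearly
      d_star <- max(floor_d, min(d_star / err^1.5, 2 * d_star0))
    }
    match_rate <- mean(res$used)

    e_sites <- res$edges
    n_end <- length(res$dangling_site)
    node_of_site <- site_node + 1L # 1-based node ids
    from <- node_of_site[e_sites[, 1] + 1L]
    to <- node_of_site[e_sites[, 2] + 1L]
    a_pts <- site_pos[e_sites[, 1] + 1L, , drop = FALSE]
    b_pts <- site_pos[e_sites[, 2] + 1L, , drop = FALSE]
    if (n_end > 0) {
      from <- c(from, node_of_site[res$dangling_site + 1L])
      to <- c(to, n_j + n_lac + seq_len(n_end))
      a_pts <- rbind(a_pts, site_pos[res$dangling_site + 1L, , drop = FALSE])
      b_pts <- rbind(b_pts, res$dangling_end)
      end_pos <- res$dangling_end
    }
    edges_nodes <- cbind(from, to)

    ## 6. tortuous edge paths -------------------------------------------
    n_e <- nrow(edges_nodes)
    alpha_cache <- new.env(parent = emptyenv())
    perp_draws <- matrix(rnorm(3 * max(n_e, 1)), ncol = 3)
    edge_paths <- vector("list", n_e)
    for (e in seq_len(n_e)) {
      a <- a_pts[e, ]; b <- b_pts[e, ]
      d <- b - a
      dl <- sqrt(sum(d^2))
      u <- perp_draws[e, ]
      u <- u - sum(u * d) * d / (dl^2)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-8) { # pathological draw: use any perpendicular
        u <- c(-d[2], d[1], 0)
        if (sum(u^2) < 1e-12) u <- c(0, -d[3], d[2])
        nu <- sqrt(sum(u^2))
      }
      u <- u / nu
      p <- tortuous_path(a, b, params$tortuosity_factor, u, alpha_cache)
      # clamp into the domain and onto the correct side of the interface
      for (ax in 1:3)
        p[, ax] <- pmin(pmax(p[, ax], 0.05), L[ax] - 0.05)
      if (iface_axis >= 0) {
        side <- a[iface_axis + 1] >= iface_pos
        p[, iface_axis + 1] <- if (side)
          pmax(p[, iface_axis + 1], iface_pos + 0.05)
        else pmin(p[, iface_axis + 1], iface_pos - 0.05)
      }
      edge_paths[[e]] <- p
    }
  }

  ## 7. assemble the graph -------------------------------------------------
  nodes <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), kind = character(),
                      lacuna_id = integer())
  if (n_j > 0)
    nodes <- rbind(nodes, data.frame(id = seq_len(n_j), x_um = jpos[, 1],
                                     y_um = jpos[, 2], z_um = jpos[, 3],
                                     kind = "junction", lacuna_id = NA_integer_))
  if (n_lac > 0)
    nodes <- rbind(nodes, data.frame(id = n_j + seq_len(n_lac),
                                     x_um = centers[, 1], y_um = centers[, 2],
                                     z_um = centers[, 3], kind = "lacuna",
                                     lacuna_id = seq_len(n_lac)))
  if (nrow(end_pos) > 0)
    nodes <- rbind(nodes, data.frame(id = n_j + n_lac + seq_len(nrow(end_pos)),
                                     x_um = end_pos[, 1], y_um = end_pos[, 2],
                                     z_um = end_pos[, 3], kind = "endpoint",
                                     lacuna_id = NA_integer_))
  edges <- data.frame(source = edges_nodes[, 1], target = edges_nodes[, 2],
                      length_um = vapply(edge_paths, polyline_length,
                                         numeric(1)))
  graph <- lcn_graph(nodes, edges, edge_paths)

  ## 8. realized statistics ------------------------------------------------
  lac_deg <- graph$nodes$degree[graph$nodes$kind == "lacuna"]
  if (n_lac > 0) shapes$degree_realized <- lac_deg
  realized <- realized_stats(graph, params)

  structure(list(
    graph = graph,
    lacunae = shapes,
    lacuna_centers = centers,
    lacuna_rotations = rots,
    region = list(slab_axis = "y",
                  unordered_fraction = params$unordered_fraction,
                  domain_size_um = L),
    interface_plane = params$interface_plane,
    realized = realized,
    params = params,
    seed = params$seed,
    metadata = list(implied_mean_edge_length_um = implied,
                    d_star_um = d_star,
                    match_rate = match_rate,
                    n_junctions = n_j, n_lacunae = n_lac)
  ), class = "lcn_truth")
}

points_in_ellipsoids <- function(pts, centers, semi, rots) {
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d <- pts - matrix(centers[i, ], nrow(pts), 3, byrow = TRUE)
    b <- d %*% rots[[i]] # body-frame coordinates (R^T d)'
    q <- (b[, 1] / semi[i, 1])^2 + (b[, 2] / semi[i, 2])^2 +
      (b[, 3] / semi[i, 3])^2
    inside <- inside | q <= 1
  }
  inside
}

realized_stats <- function(graph, params) {
  L <- params$domain_size_um
  V <- prod(L)
  f <- params$unordered_fraction
  n <- graph$nodes
  e <- graph$edges
  genuine <- n$kind == "junction" & n$degree >= 3
  mids <- if (nrow(e))
    t(vapply(graph$paths, function(p) p[ceiling(nrow(p) / 2), ], numeric(3)))
  else matrix(numeric(), 0, 3)
  e_unord <- if (nrow(e)) region_is_unordered(mids, params) else logical()
  n_unord <- region_is_unordered(cbind(n$x_um, n$y_um, n$z_um), params)
  counted <- n$kind %in% c("junction", "lacuna")
  one_region <- function(sel_e, sel_n, vol) {
    list(can_dn = sum(e$length_um[sel_e]) / vol,
         nd_nr = sum(counted & sel_n) / vol,
         mean_genuine_degree = if (any(genuine & sel_n))
           mean(n$degree[genuine & sel_n]) else NA_real_)
  }
  list(
    overall = one_region(rep(TRUE, nrow(e)), rep(TRUE, nrow(n)), V),
    ordered = if (f < 1) one_region(!e_unord, !n_unord, (1 - f) * V) else NULL,
    unordered = if (f > 0) one_region(e_unord, n_unord, f * V) else NULL
  )
}

#' @export
print.lcn_truth <- function(x, ...) {
  cat(sprintf("<lcn_truth> seed %d, domain %.0f x %.0f x %.0f um\n",
              x$seed, x$params$domain_size_um[1], x$params$domain_size_um[2],
              x$params$domain_size_um[3]))
  r <- x$realized$overall
  cat(sprintf("  realized Can.Dn %.3f um/um^3, Nd.Nr %.4f um^-3, Nd.Dg %.2f\n",
              r$can_dn, r$nd_nr, r$mean_genuine_degree))
  print(x$graph)
  invisible(x)
}
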