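#' Subvolume maps of network parameters
#'
#' Partitions space into cubic cells of volume `v_sub_um3` (edge
#' `v_sub_um3^(1/3)`, half-open intervals per axis, grid anchored at the
#' origin) and evaluates, per cell: canalicular density Can.Dn (edge paths
#' exactly clipped to the cell, length / volume, um/um^3), node number Nd.Nr
#' (junctions and lacunae whose position falls in the cell, per um^3;
#' endpoints are not counted), and node degree Nd.Dg (mean degree of genuine
#' nodes, i.e. junctions with degree >= 3; `NA` where a cell has none). A
#' cell is valid if it lies entirely inside the domain (and, if `roi_mask`
#' is given, entirely inside the ROI).
#'
#' @param graph an [lcn_graph()].
#' @param domain_size_um length-3 physical extent covered by the grid.
#' @param v_sub_um3 cell volume (um^3); default 400.
#' @param roi_mask optional `lcn_mask`; cells whose voxel footprint contains
#'   any FALSE voxel are invalid.
#' @return A data.frame of class `subvolume_map` with cell indices `ix, iy,
#'   iz` (1-based), `can_dn`, `nd_nr`, `nd_dg`, `valid`, and attributes
#'   `cell_edge_um`, `v_sub_um3`, `domain_size_um`.
#' @export
compute_subvolume_maps <- function(graph, domain_size_um, v_sub_um3 = 400,
                                   roi_mask = NULL) {
  h <- v_sub_um3^(1 / 3)
  nc <- pmax(1L, as.integer(ceiling(domain_size_um / h - 1e-9)))
  ncell <- prod(nc)

  # exact edge clipping
  len <- numeric(ncell)
  if (length(graph$paths)) {
    segs_p <- do.call(rbind, lapply(graph$paths, function(p)
      p[-nrow(p), , drop = FALSE]))
    segs_q <- do.call(rbind, lapply(graph$paths, function(p)
      p[-1, , drop = FALSE]))
    len <- cpp_clip_segments(segs_p, segs_q, h, nc)
  }

  idx <- arrayInd(seq_len(ncell), nc)
  cells <- data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3])
  cells$can_dn <- len / v_sub_um3

  n <- graph$nodes
  counted <- n$kind %in% c("junction", "lacuna")
  cells$nd_nr <- 0
  cells$nd_dg <- NA_real_
  if (any(counted)) {
    ci <- floor(cbind(n$x_um, n$y_um, n$z_um) / h)
    ingrid <- ci[, 1] >= 0 & ci[, 1] < nc[1] & ci[, 2] >= 0 &
      ci[, 2] < nc[2] & ci[, 3] >= 0 & ci[, 3] < nc[3]
    lin <- ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3]) + 1
    cnt <- tabulate(lin[counted & ingrid], nbins = ncell)
    cells$nd_nr <- cnt / v_sub_um3
    genuine <- n$kind == "junction" & n$degree >= 3 & ingrid
    if (any(genuine)) {
      sums <- tapply(n$degree[genuine], lin[genuine], sum)
      nums <- tapply(rep(1, sum(genuine)), lin[genuine], sum)
      pos <- as.integer(names(sums))
      cells$nd_dg[pos] <- as.numeric(sums / nums)
    }
  }

  # validity: fully inside the domain (and the ROI, if given)
  hi <- cbind(cells$ix, cells$iy, cells$iz) * h
  valid <- hi[, 1] <= domain_size_um[1] + 1e-9 &
    hi[, 2] <= domain_size_um[2] + 1e-9 & hi[, 3] <= domain_size_um[3] + 1e-9
  if (!is.null(roi_mask)) {
    stopifnot(inherits(roi_mask, "lcn_mask"))
    dims <- dim(roi_mask$mask)
    sp <- roi_mask$spacing_um
    for (r in which(valid)) {
      v0 <- pmax(1L, as.integer(floor((c(cells$ix[r], cells$iy[r],
                                         cells$iz[r]) - 1) * h / sp)) + 1L)
      v1 <- pmin(dims, as.integer(ceiling(c(cells$ix[r], cells$iy[r],
                                            cells$iz[r]) * h / sp)))
      if (any(v1 < v0) ||
          !all(roi_mask$mask[v0[1]:v1[1], v0[2]:v1[2], v0[3]:v1[3]]))
        valid[r] <- FALSE
    }
  }
  cells$valid <- valid
  if (!any(valid)) warning("subvolume map has no valid cells")
  attr(cells, "cell_edge_um") <- h
  attr(cells, "v_sub_um3") <- v_sub_um3
  attr(cells, "domain_size_um") <- domain_size_um
  class(cells) <- c("subvolume_map", "data.frame")
  cells
}

#' Lacunar morphometry from a segmentation
#'
#' For every labelled lacuna: volume Lc.V (voxel count x voxel volume),
#' ellipsoid-equivalent semi-axes from the second central moments of the
#' voxel cloud (eigenvalues lambda1 >= lambda2 >= lambda3; semi-axis =
#' sqrt(5 lambda), exact for a solid ellipsoid; the voxel self-covariance
#' `spacing^2 / 12` is added before the eigendecomposition), stretch Lc.St =
#' 1 - c/a, oblateness Lc.Ob = 2 (b - c)/(a - c) - 1 (0 when a - c < 1e-6
#' um, e.g. spheres), and lacunar degree Lc.Dg copied from the graph.
#' Lacunae of fewer than 10 voxels are flagged and their shape set to `NA`.
#'
#' @param seg an `lcn_seg` from [segment_lacunae()].
#' @param graph optional [lcn_graph()] supplying Lc.Dg via `lacuna_id`.
#' @return data.frame with `id`, `lc_v_um3`, `a_um`, `b_um`, `c_um`,
#'   `lc_st`, `lc_ob`, `lc_dg`, `flagged`.
#' @export
lacuna_morphometry <- function(seg, graph = NULL) {
  stopifnot(inherits(seg, "lcn_seg"))
  dims <- dim(seg$labels)
  sp <- seg$spacing_um
  voxvol <- prod(sp)
  ids <- sort(unique(seg$labels[seg$labels > 0]))
  out <- data.frame(id = integer(), lc_v_um3 = numeric(), a_um = numeric(),
                    b_um = numeric(), c_um = numeric(), lc_st = numeric(),
                    lc_ob = numeric(), lc_dg = integer(), flagged = logical())
  dg <- NULL
  if (!is.null(graph)) dg <- lacuna_degrees(graph)
  for (id in ids) {
    vox <- which(seg$labels == id)
    nv <- length(vox)
    coord <- (arrayInd(vox, dims) - 0.5) *
      matrix(sp, nv, 3, byrow = TRUE)
    lc_dg <- if (!is.null(dg) && id %in% dg$lacuna_id)
      dg$lc_dg[match(id, dg$lacuna_id)] else NA_integer_
    if (nv < 10) {
      out <- rbind(out, data.frame(id = id, lc_v_um3 = nv * voxvol,
                                   a_um = NA_real_, b_um = NA_real_,
                                   c_um = NA_real_, lc_st = NA_real_,
                                   lc_ob = NA_real_, lc_dg = lc_dg,
                                   flagged = TRUE))
      next
    }
    cc <- sweep(coord, 2, colMeans(coord))
    covm <- crossprod(cc) / nv + diag(sp^2 / 12)
    lam <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    semi <- sqrt(5 * pmax(lam, 0))
    a <- semi[1]; b <- semi[2]; c <- semi[3]
    out <- rbind(out, data.frame(
      id = id, lc_v_um3 = nv * voxvol, a_um = a, b_um = b, c_um = c,
      lc_st = 1 - c / a,
      lc_ob = if (a - c < 1e-6) 0 else 2 * (b - c) / (a - c) - 1,
      lc_dg = lc_dg, flagged = FALSE))
  }
  out
}

#' Cumulative node-degree distribution and exponential-tail fit
#'
#' Over the genuine nodes (junctions with degree >= 3), computes
#' C(x) = P(degree >= x) for integer x >= 3 and fits the decay
#' `exp(-beta (x - 3))` by unweighted least squares of `-log C(x)` against
#' `(x - 3)` through the origin, using the observed x with C(x) > 0. With all
#' nodes at degree 3 the fit is undefined and `beta` is `NaN` (with a
#' `reason` attribute).
#'
#' @param graph an [lcn_graph()], or an integer vector of degrees.
#' @return list of class `degree_fit`: `x`, `cumulative`, `beta`, `n_nodes`.
#' @export
cumulative_degree_fit <- function(graph) {
  deg <- if (inherits(graph, "lcn_graph")) genuine_degrees(graph)
  else as.integer(graph[graph >= 3])
  if (!length(deg)) stop("no genuine nodes (degree >= 3)")
  xs <- 3:max(deg)
  cum <- vapply(xs, function(x) mean(deg >= x), numeric(1))
  use <- cum > 0
  beta <- NaN
  if (max(deg) > 3) {
    xx <- xs[use] - 3
    yy <- -log(cum[use])
    beta <- sum(xx * yy) / sum(xx * xx)
  } else {
    attr(beta, "reason") <- "all genuine nodes have degree 3"
  }
  structure(list(x = xs, cumulative = cum, beta = beta,
                 n_nodes = length(deg)), class = "degree_fit")
}

#' Least-squares linear regression with Pearson R
#'
#' @param x,y numeric vectors (>= 3 finite pairs).
#' @return list of class `lcn_regression`: `slope`, `intercept`, `r`, `n`.
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::var(x) == 0) stop("undefined fit: zero variance in x")
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = stats::cor(x, y), n = length(x)),
            class = "lcn_regression")
}

#' Power-law fit by least squares on log-log axes
#'
#' Fits `y = prefactor * x^exponent` by ordinary least squares of `log y`
#' against `log x`; R is the Pearson correlation on the log scale.
#'
#' @param x,y positive numeric vectors (>= 3 finite pairs).
#' @return list of class `lcn_regression`: `exponent`, `prefactor`, `r`, `n`.
#' @export
power_law_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3) stop("need at least 3 finite positive pairs")
  fit <- linear_regression(log(x[ok]), log(y[ok]))
  structure(list(exponent = fit$slope, prefactor = exp(fit$intercept),
                 r = fit$r, n = fit$n), class = "lcn_regression")
}

#' Gaussian-smoothed normalized frequency histogram
#'
#' Counts are normalized to sum 1, convolved with a discrete Gaussian kernel
#' of SD `sigma_bins` (in bin units, truncated at 4 sigma, renormalized at
#' the boundaries so no mass is lost), and renormalized. `sigma_bins = 0`
#' returns the raw normalized histogram.
#'
#' @param values numeric vector (>= 1 finite value).
#' @param bin_edges increasing numeric vector of bin boundaries; values
#'   outside are dropped.
#' @param sigma_bins Gaussian kernel SD in bins (default 1).
#' @return list of class `smoothed_histogram`: `mid` (bin centres),
#'   `frequency` (sums to 1), `sigma_bins`.
#' @export
smoothed_histogram <- function(values, bin_edges, sigma_bins = 1) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  cnt <- graphics::hist(values[values >= bin_edges[1] &
                                 values <= bin_edges[length(bin_edges)]],
                        breaks = bin_edges, plot = FALSE)$counts
  if (sum(cnt) == 0) stop("all values fall outside the bins")
  freq <- cnt / sum(cnt)
  nb <- length(freq)
  if (sigma_bins > 0) {
    rad <- ceiling(4 * sigma_bins)
    ker <- stats::dnorm(-rad:rad, sd = sigma_bins)
    sm <- numeric(nb)
    for (i in seq_len(nb)) {
      j <- (i - rad):(i + rad)
      inb <- j >= 1 & j <= nb
      w <- ker[inb]
      sm[i] <- sum(freq[j[inb]] * w) / sum(w) * sum(ker)
    }
    freq <- sm / sum(sm)
  }
  mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  structure(list(mid = mid, frequency = freq, sigma_bins = sigma_bins),
            class = "smoothed_histogram")
}

#' Inter- vs intra-sample variability decomposition
#'
#' Intra-individual variability is the mean of the per-sample standard
#' deviations; inter-individual variability is the standard deviation of the
#' per-sample means (both with n - 1 denominators).
#'
#' @param per_sample_values list of numeric vectors, one per sample; at least
#'   2 samples of at least 2 values each.
#' @return list of class `variability_summary`: `means`, `sds`, `inter`,
#'   `intra`.
#' @export
variability_summary <- function(per_sample_values) {
  if (length(per_sample_values) < 2)
    stop("need at least 2 samples")
  if (any(vapply(per_sample_values, length, integer(1)) < 2))
    stop("each sample needs at least 2 values")
  means <- vapply(per_sample_values, mean, numeric(1))
  sds <- vapply(per_sample_values, sd, numeric(1))
  structure(list(means = means, sds = sds, inter = sd(means),
                 intra = mean(sds)), class = "variability_summary")
}

#' Two-sided Student's t-test between two groups
#'
#' Paired or independent (equal-variance) t-test, as used to compare limbs of
#' the same animals (paired) or two mouse strains (independent).
#'
#' @param a,b numeric vectors; equal lengths required when `paired`.
#' @param paired logical.
#' @return list: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
group_comparison <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (paired && length(a) != length(b))
    stop("paired mode requires equal lengths")
  ht <- t.test(a, b, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}
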