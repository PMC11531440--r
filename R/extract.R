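#' Difference-of-Gaussians adaptive binarization
#'
#' Step (i) of the image-to-network pipeline. The image is filtered with two
#' Gaussians (sigmas in um, converted per axis to voxels to respect
#' anisotropic spacing); the band-pass response `G(sigma_small) * I -
#' G(sigma_large) * I` is thresholded at `tau = mean + threshold_k * SD` of
#' its positive values. Because the large Gaussian acts as a local background
#' estimate, the threshold adapts to slowly varying illumination. The DoG of
#' a body much larger than `sigma_large` vanishes in its interior, so bulky
#' structures (lacunae) binarize as closed shells; with `fill_holes = TRUE`
#' (default) enclosed background cavities are filled so lacunae come out
#' solid.
#'
#' @param stack an [image_stack()].
#' @param sigma_small_um,sigma_large_um DoG scales in um,
#'   `0 < sigma_small < sigma_large`. The defaults (0.15 / 0.8 um) bracket
#'   the canalicular radius scale; they were calibrated on ground-truthed
#'   phantoms for recovery of faint sub-voxel tubes.
#' @param threshold_k threshold in SD units above the mean positive response.
#'   The positive-response pool is dominated by low-amplitude ripple, so a
#'   small `k` (default 0.1) already sits above it while retaining dim
#'   canalicular segments; large `k` trades completeness for specificity.
#' @param fill_holes fill background cavities not connected to the image
#'   border (6-connectivity).
#' @return A list of class `lcn_mask`: `mask` (logical 3D array),
#'   `spacing_um`, `origin_um`.
#' @export
binarize_dog <- function(stack, sigma_small_um = 0.15, sigma_large_um = 0.8,
                         threshold_k = 0.1, fill_holes = TRUE) {
  stopifnot(inherits(stack, "lcn_stack"))
  if (!(sigma_small_um > 0 && sigma_small_um < sigma_large_um))
    stop("need 0 < sigma_small_um < sigma_large_um")
  dims <- dim(stack$data)
  x <- as.numeric(stack$data)
  gs <- cpp_gauss_blur3d(x, as.integer(dims), sigma_small_um / stack$spacing_um)
  gl <- cpp_gauss_blur3d(x, as.integer(dims), sigma_large_um / stack$spacing_um)
  dog <- gs - gl
  # threshold statistics use the interior only: within the large filter's
  # support of a face, boundary reflection distorts the response and would
  # bias tau (the mask itself is still computed everywhere)
  marg <- pmin(ceiling(4 * sigma_large_um / stack$spacing_um),
               pmax(floor((dims - 1) / 2), 0))
  interior <- array(FALSE, dims)
  interior[(1 + marg[1]):(dims[1] - marg[1]),
           (1 + marg[2]):(dims[2] - marg[2]),
           (1 + marg[3]):(dims[3] - marg[3])] <- TRUE
  dog_in <- dog[interior]
  pos <- dog_in[dog_in > 0]
  if (length(pos) < 2) {
    mask <- array(FALSE, dims)
  } else {
    tau <- mean(pos) + threshold_k * sd(pos)
    mask <- array(dog > tau, dims)
    if (fill_holes && any(mask)) {
      bg <- cpp_label_components(!mask, as.integer(dims), 6L)
      border <- unique(c(bg[1, , ], bg[dims[1], , ], bg[, 1, ], bg[, dims[2], ],
                         bg[, , 1], bg[, , dims[3]]))
      border <- border[border > 0]
      hole <- !(bg %in% c(0L, border))
      mask <- mask | array(hole, dims)
    }
  }
  structure(list(mask = mask, spacing_um = stack$spacing_um,
                 origin_um = stack$origin_um), class = "lcn_mask")
}

#' Segment lacunae from canaliculi by local thickness
#'
#' Step (ii). "Bulkiness" is measured by the Euclidean distance transform (in
#' um, anisotropic): voxels with a local radius of at least
#' `thickness_radius_um` seed lacuna bodies, which are reconstructed as the
#' union of the maximal inscribed balls centred on the seeds (medial-axis
#' reconstruction) intersected with the foreground. Reconstructed components
#' with volume >= `min_lacuna_volume_um3` are labelled as lacunae (ids 1..K,
#' in decreasing volume); all remaining foreground is canaliculus.
#'
#' @param mask an `lcn_mask` from [binarize_dog()].
#' @param thickness_radius_um seed radius (um); 1 um separates ~0.15 um
#'   tubes from multi-um lacunae by an order of magnitude.
#' @param min_lacuna_volume_um3 minimum lacuna volume (um^3).
#' @return A list of class `lcn_seg`: `labels` (integer 3D array; 0 =
#'   background, -1 = canaliculus, k >= 1 = lacuna k), `spacing_um`,
#'   `lacunae` (data.frame id, voxels, volume_um3, centroid x/y/z um).
#' @export
segment_lacunae <- function(mask, thickness_radius_um = 1.0,
                            min_lacuna_volume_um3 = 50) {
  stopifnot(inherits(mask, "lcn_mask"))
  dims <- dim(mask$mask)
  voxvol <- prod(mask$spacing_um)
  labels <- array(0L, dims)
  labels[mask$mask] <- -1L
  lac_tab <- data.frame(id = integer(), voxels = integer(),
                        volume_um3 = numeric(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric())
  if (any(mask$mask)) {
    dt2 <- cpp_sq_edt(mask$mask, as.integer(dims), mask$spacing_um)
    dt <- sqrt(pmax(dt2, 0))
    core <- which(!is.na(dt) & dt >= thickness_radius_um)
    if (length(core)) {
      cidx <- arrayInd(core, dims) - 1L
      body <- cpp_stamp_balls(cidx, dt[core], as.integer(dims),
                              mask$spacing_um)
      body <- array(body & mask$mask, dims)
      comp <- cpp_label_components(body, as.integer(dims), 26L)
      sizes <- tabulate(comp[comp > 0])
      keep <- which(sizes * voxvol >= min_lacuna_volume_um3)
      if (length(keep)) {
        ord <- keep[order(sizes[keep], decreasing = TRUE)]
        for (r in seq_along(ord)) {
          vox <- which(comp == ord[r])
          labels[vox] <- r
          ci <- colMeans(arrayInd(vox, dims))
          lac_tab <- rbind(lac_tab,
                           data.frame(id = r, voxels = length(vox),
                                      volume_um3 = length(vox) * voxvol,
                                      x_um = (ci[1] - 0.5) * mask$spacing_um[1],
                                      y_um = (ci[2] - 0.5) * mask$spacing_um[2],
                                      z_um = (ci[3] - 0.5) * mask$spacing_um[3]))
        }
      }
    }
  }
  structure(list(labels = labels, spacing_um = mask$spacing_um,
                 origin_um = mask$origin_um, lacunae = lac_tab),
            class = "lcn_seg")
}

#' Skeletonize the canalicular phase of a segmentation
#'
#' Step (iii). Topology-preserving sequential thinning (simple-point deletion
#' with endpoint protection, 26-connectivity for the foreground) of the
#' canaliculus label. Lacuna voxels are anchors: they count as foreground for
#' the topology test but are never thinned, so skeleton branches remain
#' attached to lacuna surfaces.
#'
#' @param seg an `lcn_seg` from [segment_lacunae()].
#' @return A list of class `lcn_skel`: `skel` (logical 3D array),
#'   `spacing_um`, and the originating `seg`.
#' @export
skeletonize_mask <- function(seg) {
  stopifnot(inherits(seg, "lcn_seg"))
  dims <- dim(seg$labels)
  canal <- seg$labels == -1L
  anchor <- seg$labels > 0L
  skel <- cpp_thin3d(canal, anchor, as.integer(dims))
  structure(list(skel = array(skel, dims), spacing_um = seg$spacing_um,
                 origin_um = seg$origin_um, seg = seg), class = "lcn_skel")
}

#' Decompose a skeleton into branch paths and smooth them
#'
#' Step (iv). The skeleton is split into simple voxel chains between terminal
#' voxels (junction clusters, free endpoints and lacuna attachments). Each
#' chain of at least 4 points is replaced by a cubic smoothing spline fitted
#' per coordinate against cumulative chord length; endpoints are pinned and
#' the fit is rejected (progressively stiffened, ultimately falling back to
#' the raw polyline) if any point moves by more than one voxel diagonal.
#' Chains with fewer than 4 points keep their polyline. Arc length is
#' computed on a dense resampling of the smoothed curve (<= 0.1 um spacing).
#'
#' @param skel an `lcn_skel` from [skeletonize_mask()].
#' @return A list of class `lcn_branches`: `paths` (list of dense (n x 3)
#'   matrices, um), `ends` (matrix: kind1, id1, kind2, id2 with kind 0 =
#'   endpoint, 1 = junction cluster, 2 = lacuna), `clusters` (junction
#'   cluster centroids, um), `lengths_um`, `n_cycle_voxels`.
#' @export
smooth_branches <- function(skel) {
  stopifnot(inherits(skel, "lcn_skel"))
  dims <- dim(skel$skel)
  seg <- skel$seg
  tr <- cpp_trace_branches(skel$skel, seg$labels * (seg$labels > 0L),
                           as.integer(dims))
  spacing <- skel$spacing_um
  vox_diag <- sqrt(sum(spacing^2))
  paths <- vector("list", length(tr$paths))
  for (i in seq_along(tr$paths)) {
    vox <- tr$paths[[i]]
    pts <- (vox + 0.5) * matrix(spacing, nrow(vox), 3, byrow = TRUE)
    paths[[i]] <- smooth_path(pts, vox_diag)
  }
  clusters <- tr$clusters
  if (nrow(clusters))
    clusters[, 1:3] <- (clusters[, 1:3] + 0.5) *
      matrix(spacing, nrow(clusters), 3, byrow = TRUE)
  structure(list(paths = paths, ends = tr$ends, clusters = clusters,
                 lengths_um = vapply(paths, polyline_length, numeric(1)),
                 n_cycle_voxels = tr$n_cycle_voxels,
                 spacing_um = spacing, seg = seg), class = "lcn_branches")
}

# cubic smoothing spline of one voxel chain, endpoint-pinned,
# displacement-guarded; returns a dense polyline (<= 0.1 um spacing)
smooth_path <- function(pts, vox_diag) {
  n <- nrow(pts)
  t0 <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (n < 4 || t0[n] < 1e-9) return(pts)
  t0 <- t0 / t0[n]
  df <- max(4, ceiling(n / 2))
  repeat {
    fits <- vector("list", 3)
    fit <- matrix(NA_real_, n, 3)
    ok <- TRUE
    for (d in 1:3) {
      sp <- try(stats::smooth.spline(t0, pts[, d], df = min(df, n),
                                     all.knots = TRUE), silent = TRUE)
      if (inherits(sp, "try-error")) { ok <- FALSE; break }
      fits[[d]] <- sp
      fit[, d] <- predict(sp, t0)$y
    }
    if (ok) {
      # pin the endpoints with a linear correction
      c1 <- pts[1, ] - fit[1, ]
      c2 <- pts[n, ] - fit[n, ]
      fit <- fit + outer(1 - t0, c1) + outer(t0, c2)
      if (max(sqrt(rowSums((fit - pts)^2))) <= vox_diag) {
        # dense resampling for arc length
        total <- sum(sqrt(rowSums(diff(fit)^2)))
        m <- max(n, ceiling(total / 0.1) + 1)
        tt <- seq(0, 1, length.out = m)
        dense <- matrix(NA_real_, m, 3)
        for (d in 1:3) dense[, d] <- predict(fits[[d]], tt)$y
        dense <- dense + outer(1 - tt, c1) + outer(tt, c2)
        dense[1, ] <- pts[1, ]
        dense[m, ] <- pts[n, ]
        return(dense)
      }
    }
    df <- df + 2
    if (df >= n) return(pts)
  }
}

#' Translate smoothed branches into a spatial network
#'
#' Step (v). Junction voxel clusters become junction nodes at their centroids;
#' clusters closer than `merge_radius_um` are collapsed (single linkage) into
#' one node. Lacuna attachments connect to one lacuna node per segmented
#' lacuna (at its centroid; edge geometry ends at the lacuna surface so edge
#' length counts only canalicular length). Free chain ends become endpoint
#' nodes. Self-loop branches are dropped. Then, iteratively: spur edges
#' incident to a degree-1 endpoint and shorter than `prune_length_um` are
#' removed, and junction nodes left with degree 2 are dissolved by
#' concatenating their two edges. The lacunar degree Lc.Dg is the number of
#' canaliculi incident to each lacuna node.
#'
#' @param branches an `lcn_branches` from [smooth_branches()].
#' @param merge_radius_um junction-cluster merge radius.
#' @param prune_length_um maximum length of a spur to prune.
#' @param attach_radius_um free branch ends closer than this to a lacuna body
#'   are reconnected to the lacuna (bridging the binarization shadow around
#'   bright lacunae); 0 disables.
#' @return An [lcn_graph()].
#' @export
build_graph <- function(branches, merge_radius_um = 0.5,
                        prune_length_um = 0.5, attach_radius_um = 5.0) {
  stopifnot(inherits(branches, "lcn_branches"))
  seg <- branches$seg
  cl <- branches$clusters
  ncl <- nrow(cl)

  # merge junction clusters within merge_radius (single linkage)
  cl_node <- seq_len(max(ncl, 0))
  if (ncl > 1) {
    pos <- cl[, 1:3, drop = FALSE]
    pairs <- which(as.matrix(stats::dist(pos)) <= merge_radius_um,
                   arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
      g <- igraph::add_vertices(g, max(0, ncl - igraph::vcount(g)))
      cl_node <- igraph::components(g)$membership
    }
  }
  n_jn <- if (ncl) max(cl_node) else 0L
  jn_pos <- matrix(0, n_jn, 3)
  if (ncl) {
    w <- cl[, 4]
    for (k in seq_len(n_jn)) {
      sel <- cl_node == k
      jn_pos[k, ] <- colSums(cl[sel, 1:3, drop = FALSE] * w[sel]) / sum(w[sel])
    }
  }

  lac <- seg$lacunae
  n_lac <- nrow(lac)
  nodes <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), kind = character(),
                      lacuna_id = integer())
  if (n_jn > 0)
    nodes <- rbind(nodes, data.frame(id = seq_len(n_jn), x_um = jn_pos[, 1],
                                     y_um = jn_pos[, 2], z_um = jn_pos[, 3],
                                     kind = "junction",
                                     lacuna_id = NA_integer_))
  if (n_lac > 0)
    nodes <- rbind(nodes, data.frame(id = n_jn + seq_len(n_lac),
                                     x_um = lac$x_um, y_um = lac$y_um,
                                     z_um = lac$z_um, kind = "lacuna",
                                     lacuna_id = lac$id))
  next_id <- n_jn + n_lac

  ends <- branches$ends
  src <- dst <- integer(0)
  paths <- list()
  extra_nodes <- list()
  for (i in seq_along(branches$paths)) {
    p <- branches$paths[[i]]
    node_at <- integer(2)
    for (side in 1:2) {
      kind <- ends[i, 2 * side - 1]
      id <- ends[i, 2 * side]
      if (kind == 1 && id >= 1) {
        node_at[side] <- cl_node[id]
        # extend geometry to the merged node centroid
        cpos <- jn_pos[cl_node[id], ]
        p <- if (side == 1) rbind(cpos, p) else rbind(p, cpos)
      } else if (kind == 2 && id >= 1 && id <= n_lac) {
        node_at[side] <- n_jn + id
      } else {
        next_id <- next_id + 1L
        ep <- if (side == 1) p[1, ] else p[nrow(p), ]
        extra_nodes[[length(extra_nodes) + 1L]] <-
          data.frame(id = next_id, x_um = ep[1], y_um = ep[2], z_um = ep[3],
                     kind = "endpoint", lacuna_id = NA_integer_)
        node_at[side] <- next_id
      }
    }
    if (node_at[1] == node_at[2]) next # self-loop artifact
    src <- c(src, node_at[1])
    dst <- c(dst, node_at[2])
    paths[[length(paths) + 1L]] <- p
  }
  if (length(extra_nodes)) nodes <- rbind(nodes, do.call(rbind, extra_nodes))
  edges <- data.frame(source = src, target = dst,
                      length_um = vapply(paths, polyline_length, numeric(1)))
  # drop endpoint nodes orphaned by self-loop removal
  used <- nodes$kind %in% c("junction", "lacuna") |
    nodes$id %in% c(edges$source, edges$target)
  nodes <- nodes[used, , drop = FALSE]
  g <- lcn_graph(nodes, edges, paths)
  g <- snap_endpoints_to_lacunae(g, seg, attach_radius_um)
  prune_graph(g, prune_length_um)
}

# Reconnect free branch ends to nearby lacunae. The adaptive binarization
# suppresses faint tubes in a halo around each bright lacuna (the large
# Gaussian inflates the local background there), so canaliculi emanating from
# a lacuna binarize with a gap at the surface. Endpoint nodes closer than
# attach_radius_um to a lacuna's voxel body are rewired onto the lacuna node,
# with a straight bridge appended to the nearest body voxel.
snap_endpoints_to_lacunae <- function(g, seg, attach_radius_um) {
  lac <- seg$lacunae
  if (!nrow(lac) || attach_radius_um <= 0) return(g)
  dims <- dim(seg$labels)
  sp <- seg$spacing_um
  lac_vox <- lapply(lac$id, function(id)
    (arrayInd(which(seg$labels == id), dims) - 0.5) *
      matrix(sp, sum(seg$labels == id), 3, byrow = TRUE))
  # conservative per-lacuna reach for a cheap prefilter
  reach <- vapply(seq_along(lac_vox), function(i)
    max(sqrt(colSums((t(lac_vox[[i]]) - c(lac$x_um[i], lac$y_um[i],
                                          lac$z_um[i]))^2))), numeric(1)) +
    attach_radius_um + 1
  n <- g$nodes
  ep_ids <- n$id[n$kind == "endpoint" & n$degree == 1]
  lac_node_of <- function(id) n$id[match(id, n$lacuna_id)]
  for (nid in ep_ids) {
    v <- match(nid, n$id)
    pos <- c(n$x_um[v], n$y_um[v], n$z_um[v])
    best_d <- attach_radius_um
    best_i <- 0L
    best_pt <- NULL
    for (i in seq_len(nrow(lac))) {
      if (sqrt(sum((pos - c(lac$x_um[i], lac$y_um[i], lac$z_um[i]))^2)) >
          reach[i]) next
      d2 <- colSums((t(lac_vox[[i]]) - pos)^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= best_d) {
        best_d <- sqrt(d2[j])
        best_i <- i
        best_pt <- lac_vox[[i]][j, ]
      }
    }
    if (best_i == 0L) next
    lid <- lac_node_of(lac$id[best_i])
    ei <- which(g$edges$source == nid | g$edges$target == nid)[1]
    if (is.na(ei)) next
    other <- if (g$edges$source[ei] == nid) g$edges$target[ei]
    else g$edges$source[ei]
    if (other == lid) next # would become a self-loop
    p <- g$paths[[ei]]
    if (g$edges$source[ei] == nid) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    # radial gate: a genuine attachment approaches the surface head-on;
    # halo-ring artifacts run tangential to it and must not be snapped
    if (best_d > 1e-6 && nrow(p) >= 2) {
      kb <- max(1, nrow(p) - 4)
      tangent <- p[nrow(p), ] - p[kb, ]
      nt <- sqrt(sum(tangent^2))
      bridge <- (best_pt - pos) / best_d
      if (nt > 1e-6 && sum(tangent / nt * bridge) < 0.1) next
    }
    p <- rbind(p, best_pt) # now runs other -> endpoint -> lacuna surface
    g$edges$source[ei] <- other
    g$edges$target[ei] <- lid
    g$edges$length_um[ei] <- polyline_length(p)
    g$paths[[ei]] <- p
    g$nodes <- g$nodes[g$nodes$id != nid, , drop = FALSE]
    n <- g$nodes
  }
  recompute_degrees(g)
}

prune_graph <- function(g, prune_length_um) {
  repeat {
    changed <- FALSE
    n <- g$nodes; e <- g$edges
    # spurs: short edges hanging on a degree-1 non-lacuna node
    deg1 <- n$id[n$degree == 1 & n$kind != "lacuna"]
    if (length(deg1) && nrow(e)) {
      hang <- (e$source %in% deg1 | e$target %in% deg1) &
        e$length_um < prune_length_um
      # do not prune a spur whose other end is a lacuna-lacuna bridge etc.
      if (any(hang)) {
        keep <- !hang
        g$edges <- e[keep, , drop = FALSE]
        g$paths <- g$paths[keep]
        g <- recompute_degrees(g)
        changed <- TRUE
      }
    }
    # dissolve degree-2 junction nodes
    n <- g$nodes; e <- g$edges
    d2 <- n$id[n$degree == 2 & n$kind == "junction"]
    if (length(d2)) {
      nid <- d2[1]
      ei <- which(e$source == nid | e$target == nid)
      if (length(ei) == 2) {
        e1 <- ei[1]; e2 <- ei[2]
        p1 <- g$paths[[e1]]; p2 <- g$paths[[e2]]
        a1 <- if (e$source[e1] == nid) e$target[e1] else e$source[e1]
        a2 <- if (e$source[e2] == nid) e$target[e2] else e$source[e2]
        # paths run source -> target; build a1 -> nid -> a2
        if (e$source[e1] == nid) p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
        if (e$source[e2] != nid) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
        newp <- rbind(p1, p2[-1, , drop = FALSE])
        if (a1 == a2) { # the two edges form a loop: drop both
          keep <- setdiff(seq_len(nrow(e)), ei)
          g$edges <- e[keep, , drop = FALSE]
          g$paths <- g$paths[keep]
        } else {
          newe <- data.frame(source = a1, target = a2,
                             length_um = polyline_length(newp))
          keep <- setdiff(seq_len(nrow(e)), ei)
          g$edges <- rbind(e[keep, , drop = FALSE], newe)
          g$paths <- c(g$paths[keep], list(newp))
        }
        g$nodes <- g$nodes[g$nodes$id != nid, , drop = FALSE]
        g <- recompute_degrees(g)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # drop nodes orphaned by pruning; reclassify leftover degree<3 junctions
  # so every junction node is genuine or gone
  n <- g$nodes
  lone <- n$degree == 0 & n$kind != "lacuna"
  g$nodes <- n[!lone, , drop = FALSE]
  n <- g$nodes
  g$nodes$kind[n$kind == "junction" & n$degree < 3] <- "endpoint"
  recompute_degrees(g)
}

#' Run the full image-to-network extraction pipeline
#'
#' Chains [binarize_dog()], [segment_lacunae()], [skeletonize_mask()],
#' [smooth_branches()] and [build_graph()] with a single configuration.
#'
#' @param stack an [image_stack()].
#' @param sigma_small_um,sigma_large_um,threshold_k see [binarize_dog()].
#' @param thickness_radius_um,min_lacuna_volume_um3 see [segment_lacunae()].
#' @param merge_radius_um,prune_length_um,attach_radius_um see
#'   [build_graph()].
#' @return list with `graph`, `mask`, `seg`, `skel`, `branches`.
#' @export
extract_network <- function(stack, sigma_small_um = 0.15,
                            sigma_large_um = 0.8,
                            threshold_k = 0.1, thickness_radius_um = 1.0,
                            min_lacuna_volume_um3 = 50,
                            merge_radius_um = 0.5, prune_length_um = 0.5,
                            attach_radius_um = 5.0) {
  mask <- binarize_dog(stack, sigma_small_um, sigma_large_um, threshold_k)
  seg <- segment_lacunae(mask, thickness_radius_um, min_lacuna_volume_um3)
  skel <- skeletonize_mask(seg)
  branches <- smooth_branches(skel)
  graph <- build_graph(branches, merge_radius_um, prune_length_um,
                       attach_radius_um)
  list(graph = graph, mask = mask, seg = seg, skel = skel,
       branches = branches)
}
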