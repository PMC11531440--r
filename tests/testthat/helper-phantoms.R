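# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small ground truth used by several metric tests (no raster needed)
small_truth <- function() {
  cached("small_truth", function()
    generate_ground_truth(generator_params(domain_size_um = c(30, 30, 30),
                                           lacuna_number_density = 4e-5,
                                           seed = 7)))
}

# a tiny rasterized + degraded phantom for pipeline tests
mini_phantom <- function() {
  cached("mini_phantom", function() {
    p <- generator_params(domain_size_um = c(25, 25, 25),
                          lacuna_number_density = 6e-5, seed = 13)
    tr <- generate_ground_truth(p)
    list(params = p, truth = tr, image = degrade(rasterize(tr, p), p))
  })
}

# analytic straight tube along x: returns stack + path
make_tube_stack <- function(length_um = 14, radius_um = 0.3,
                            box_um = c(20, 8, 8),
                            spacing = c(0.379, 0.379, 0.340)) {
  dims <- as.integer(ceiling(box_um / spacing))
  x0 <- (box_um[1] - length_um) / 2
  path <- cbind(seq(x0, x0 + length_um, by = 0.25),
                box_um[2] / 2, box_um[3] / 2)
  img <- lcntools:::cpp_raster_tubes(list(path), radius_um, dims, spacing,
                                     numeric(prod(dims)))
  dim(img) <- dims
  list(stack = image_stack(img, spacing), path = path, dims = dims,
       spacing = spacing)
}

# Y-shaped tube: one stem, two arms meeting at (10, 10, 4)
make_y_stack <- function(radius_um = 0.3, spacing = c(0.379, 0.379, 0.340)) {
  box <- c(20, 20, 8)
  dims <- as.integer(ceiling(box / spacing))
  paths <- list(cbind(seq(2, 10, by = 0.25), 10, 4),
                rbind(c(10, 10, 4), c(17, 16, 4)),
                rbind(c(10, 10, 4), c(17, 4, 4)))
  img <- lcntools:::cpp_raster_tubes(paths, radius_um, dims, spacing,
                                     numeric(prod(dims)))
  dim(img) <- dims
  list(stack = image_stack(img, spacing), paths = paths, dims = dims,
       spacing = spacing)
}

# analytic voxelized ellipsoid segmentation (axis-aligned, no imaging):
# labels array with one lacuna of semi-axes abc centred in the box
make_ellipsoid_seg <- function(abc = c(9, 5, 3), box_um = c(24, 16, 12),
                               spacing = c(0.379, 0.379, 0.340)) {
  dims <- as.integer(ceiling(box_um / spacing))
  ctr <- box_um / 2
  img <- lcntools:::cpp_raster_ellipsoids(matrix(ctr, 1),
                                          matrix(abc, 1), list(diag(3)),
                                          dims, spacing, numeric(prod(dims)))
  dim(img) <- dims
  labels <- array(0L, dims)
  labels[img > 0.5] <- 1L
  vox <- which(labels == 1L)
  ci <- colMeans(arrayInd(vox, dims))
  structure(list(labels = labels, spacing_um = spacing,
                 origin_um = c(0, 0, 0),
                 lacunae = data.frame(id = 1L, voxels = length(vox),
                                      volume_um3 = length(vox) * prod(spacing),
                                      x_um = (ci[1] - 0.5) * spacing[1],
                                      y_um = (ci[2] - 0.5) * spacing[2],
                                      z_um = (ci[3] - 0.5) * spacing[3])),
            class = "lcn_seg")
}
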