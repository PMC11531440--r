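test_that("a constant stack binarizes to an empty mask", {
  st <- image_stack(array(0.5, c(20, 20, 20)))
  m <- binarize_dog(st)
  expect_false(any(m$mask))
})

test_that("raising threshold_k never increases the foreground", {
  ph <- mini_phantom()
  counts <- vapply(c(0, 0.5, 1, 2), function(k)
    sum(binarize_dog(ph$image, threshold_k = k, fill_holes = FALSE)$mask),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a noise-free blurred tube binarizes with Dice >= 0.7", {
  tube <- make_tube_stack(length_um = 14, radius_um = 0.15)
  p <- generator_params(noise_sd = 0, background_gradient = 0)
  blurred <- degrade(tube$stack, p)
  m <- binarize_dog(blurred)
  truth <- tube$stack$data > 0.05
  dice <- 2 * sum(m$mask & truth) / (sum(m$mask) + sum(truth))
  expect_gte(dice, 0.7)
})

test_that("the DoG threshold adapts to a linear background gradient", {
  tube <- make_tube_stack(length_um = 14, radius_um = 0.15)
  p0 <- generator_params(noise_sd = 0, background_gradient = 0)
  p1 <- generator_params(noise_sd = 0, background_gradient = 0.01)
  m0 <- binarize_dog(degrade(tube$stack, p0))
  m1 <- binarize_dog(degrade(tube$stack, p1))
  dice <- 2 * sum(m0$mask & m1$mask) / (sum(m0$mask) + sum(m1$mask))
  expect_gte(dice, 0.95)
})

test_that("segmentation separates lacunae from canaliculi by thickness", {
  # a bare thin tube contains no lacuna
  tube <- make_tube_stack(length_um = 14, radius_um = 0.15)
  m <- binarize_dog(degrade(tube$stack,
                            generator_params(noise_sd = 0,
                                             background_gradient = 0)))
  seg <- segment_lacunae(m)
  expect_equal(nrow(seg$lacunae), 0)
  expect_true(all(seg$labels[m$mask] == -1L))
  # an ellipsoid with attached tubes segments as exactly one lacuna
  sp <- c(0.379, 0.379, 0.340)
  dims <- as.integer(ceiling(c(24, 16, 12) / sp))
  img <- lcntools:::cpp_raster_ellipsoids(matrix(c(12, 8, 6), 1),
                                          matrix(c(9, 5, 3), 1), list(diag(3)),
                                          dims, sp, numeric(prod(dims)))
  img <- lcntools:::cpp_raster_tubes(list(rbind(c(21.2, 8, 6), c(23.5, 8, 6))),
                                     0.15, dims, sp, img)
  dim(img) <- dims
  mask <- structure(list(mask = img > 0.4, spacing_um = sp,
                         origin_um = c(0, 0, 0)), class = "lcn_mask")
  seg2 <- segment_lacunae(mask)
  expect_equal(nrow(seg2$lacunae), 1)
  expect_lt(abs(seg2$lacunae$volume_um3 / (4 / 3 * pi * 9 * 5 * 3) - 1), 0.10)
  # empty mask -> empty segmentation
  empty <- structure(list(mask = array(FALSE, c(5, 5, 5)),
                          spacing_um = sp, origin_um = c(0, 0, 0)),
                     class = "lcn_mask")
  expect_equal(nrow(segment_lacunae(empty)$lacunae), 0)
})

test_that("a straight cylinder skeletonizes to its centreline", {
  tube <- make_tube_stack(length_um = 14, radius_um = 0.3)
  mask <- structure(list(mask = tube$stack$data > 0.3,
                         spacing_um = tube$spacing, origin_um = c(0, 0, 0)),
                    class = "lcn_mask")
  seg <- segment_lacunae(mask)
  sk <- skeletonize_mask(seg)
  idx <- which(sk$skel, arr.ind = TRUE)
  pos <- (idx - 0.5) * matrix(tube$spacing, nrow(idx), 3, byrow = TRUE)
  # within one voxel of the analytic axis y = z = 4
  expect_lt(max(abs(pos[, 2] - 4)), 2 * tube$spacing[2])
  expect_lt(max(abs(pos[, 3] - 4)), 2 * tube$spacing[3])
  br <- smooth_branches(sk)
  expect_equal(length(br$paths), 1)
  expect_equal(sort(br$ends[1, c(1, 3)]), c(0, 0)) # two free endpoints
  # thinness: no 2x2x2 block is fully skeletal
  s <- sk$skel
  d <- dim(s)
  blocks <- s[-d[1], -d[2], -d[3]] & s[-1, -d[2], -d[3]] &
    s[-d[1], -1, -d[3]] & s[-1, -1, -d[3]] &
    s[-d[1], -d[2], -1] & s[-1, -d[2], -1] &
    s[-d[1], -1, -1] & s[-1, -1, -1]
  expect_false(any(blocks))
})

test_that("a Y-tube yields one junction with three branches", {
  y <- make_y_stack()
  mask <- structure(list(mask = y$stack$data > 0.3, spacing_um = y$spacing,
                         origin_um = c(0, 0, 0)), class = "lcn_mask")
  seg <- segment_lacunae(mask)
  sk <- skeletonize_mask(seg)
  br <- smooth_branches(sk)
  expect_equal(nrow(br$clusters), 1)
  expect_equal(length(br$paths), 3)
  g <- build_graph(br)
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  expect_equal(g$nodes$degree[g$nodes$kind == "junction"], 3)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(g$edges), 3)
})

test_that("an empty canaliculus phase gives an empty skeleton", {
  seg <- structure(list(labels = array(0L, c(8, 8, 8)),
                        spacing_um = c(0.379, 0.379, 0.340),
                        origin_um = c(0, 0, 0),
                        lacunae = data.frame()), class = "lcn_seg")
  sk <- skeletonize_mask(seg)
  expect_false(any(sk$skel))
})

test_that("smoothing keeps lines exact and shortens staircases", {
  vd <- sqrt(sum(c(0.379, 0.379, 0.340)^2))
  # collinear path of length 10: spline of a line is the line
  line <- cbind(seq(0, 10, by = 0.5), 0, 0)
  sm <- lcntools:::smooth_path(line, vd)
  expect_equal(lcntools:::polyline_length(sm), 10, tolerance = 1e-6)
  # 3-point path: degenerate rule returns the polyline untouched
  p3 <- cbind(c(0, 1, 2), c(0, 0.3, 0), 0)
  expect_identical(lcntools:::smooth_path(p3, vd), p3)
  # 45-degree staircase: smoothed length below the voxel polyline, above chord
  n <- 30
  stair <- cbind(rep(seq_len(n), each = 2)[-1] * 0.379,
                 rep(seq_len(n), each = 2)[-2 * n] * 0.379, 0)
  sm2 <- lcntools:::smooth_path(stair, vd)
  chord <- sqrt(sum((stair[nrow(stair), ] - stair[1, ])^2))
  expect_lt(lcntools:::polyline_length(sm2), lcntools:::polyline_length(stair))
  expect_gte(lcntools:::polyline_length(sm2), chord)
})

test_that("an isolated lacuna yields one lacuna node with zero degree", {
  seg <- make_ellipsoid_seg()
  sk <- skeletonize_mask(seg)
  br <- smooth_branches(sk)
  g <- build_graph(br)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(g$nodes$kind, "lacuna")
  expect_equal(g$nodes$degree, 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("degree sum equals twice the edge count on extracted graphs", {
  ph <- mini_phantom()
  g <- extract_network(ph$image)$graph
  expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
  # determinism of the full pipeline
  g2 <- extract_network(ph$image)$graph
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})
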