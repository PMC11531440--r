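cell_h <- 400^(1 / 3)

test_that("an edge-free graph has zero canalicular density everywhere", {
  g <- lcn_graph(data.frame(id = 1L, x_um = 5, y_um = 5, z_um = 5,
                            kind = "junction"))
  m <- compute_subvolume_maps(g, rep(2 * cell_h, 3))
  expect_true(all(m$can_dn == 0))
})

test_that("a cell-spanning canaliculus gives the analytic cell density", {
  g <- lcn_graph(
    data.frame(id = 1:2, x_um = c(0, cell_h), y_um = cell_h / 2,
               z_um = cell_h / 2, kind = "endpoint"),
    data.frame(source = 1L, target = 2L, length_um = cell_h),
    list(cbind(c(0, cell_h), cell_h / 2, cell_h / 2)))
  m <- compute_subvolume_maps(g, rep(cell_h, 3))
  expect_equal(m$can_dn[1], cell_h / 400, tolerance = 1e-12)
})

test_that("cell node degree averages genuine nodes only", {
  nodes <- data.frame(id = 1:3,
                      x_um = c(1, 2, 3), y_um = 1, z_um = 1,
                      kind = c("junction", "junction", "endpoint"))
  g <- lcn_graph(nodes)
  g$nodes$degree <- c(3L, 4L, 1L) # constructed degrees
  m <- compute_subvolume_maps(g, rep(cell_h, 3))
  expect_equal(m$nd_dg[1], 3.5)
  expect_equal(m$nd_nr[1], 2 / 400) # endpoint not counted
})

test_that("clipped lengths are conserved across the subvolume map", {
  tr <- small_truth()
  m <- compute_subvolume_maps(tr$graph, rep(ceiling(30 / cell_h) * cell_h, 3))
  expect_equal(sum(m$can_dn) * 400, total_length(tr$graph),
               tolerance = 1e-6)
})

test_that("cells outside an ROI mask are invalid", {
  g <- lcn_graph()
  roi <- structure(list(mask = array(c(TRUE, FALSE)[c(1, 1, 1, 1, 1, 1, 1, 2)],
                                     c(2, 2, 2)),
                        spacing_um = rep(cell_h, 3), origin_um = c(0, 0, 0)),
                   class = "lcn_mask")
  expect_warning(m <- compute_subvolume_maps(g, rep(2 * cell_h, 3),
                                             roi_mask = roi), NA)
  expect_equal(sum(m$valid), 7)
})

test_that("ellipsoid morphometry recovers volume, stretch and oblateness", {
  seg <- make_ellipsoid_seg(abc = c(9, 5, 3))
  mo <- lacuna_morphometry(seg)
  expect_equal(nrow(mo), 1)
  expect_lt(abs(mo$lc_v_um3 / (4 / 3 * pi * 9 * 5 * 3) - 1), 0.05)
  expect_equal(mo$lc_st, 1 - 3 / 9, tolerance = 0.03)
  expect_equal(mo$lc_ob, 2 * (5 - 3) / (9 - 3) - 1, tolerance = 0.15)
})

test_that("a voxelized sphere is nearly unstretched", {
  seg <- make_ellipsoid_seg(abc = c(4, 4, 4), box_um = c(12, 12, 12))
  mo <- lacuna_morphometry(seg)
  expect_lt(mo$lc_st, 0.05)
})

test_that("exactly degenerate shapes take oblateness zero by rule", {
  # a symmetric voxel cube on an isotropic grid: eigenvalues exactly equal
  labels <- array(0L, c(13, 13, 13))
  labels[3:11, 3:11, 3:11] <- 1L
  seg <- structure(list(labels = labels, spacing_um = c(0.4, 0.4, 0.4),
                        origin_um = c(0, 0, 0), lacunae = data.frame()),
                   class = "lcn_seg")
  mo <- lacuna_morphometry(seg)
  expect_equal(mo$lc_st, 0)
  expect_equal(mo$lc_ob, 0)
})

test_that("tiny lacunae are flagged with undefined shape", {
  labels <- array(0L, c(6, 6, 6))
  labels[3, 3, 3:4] <- 1L
  seg <- structure(list(labels = labels, spacing_um = c(0.379, 0.379, 0.340),
                        origin_um = c(0, 0, 0), lacunae = data.frame()),
                   class = "lcn_seg")
  mo <- lacuna_morphometry(seg)
  expect_true(mo$flagged)
  expect_true(is.na(mo$lc_st))
})

test_that("generator-default lacunae have stretch in the 0.3-0.8 range", {
  set.seed(42)
  sh <- sample_lacuna_shapes(200, generator_params())
  expect_true(all(sh$stretch >= 0.3 & sh$stretch <= 0.8))
})

test_that("the cumulative degree fit matches its closed-form oracle", {
  f <- cumulative_degree_fit(c(3L, 3L, 3L, 4L, 5L))
  expect_equal(f$cumulative, c(1, 0.4, 0.2))
  # least squares of -log C through the origin, computed by hand
  expect_equal(f$beta, (1 * (-log(0.4)) + 2 * (-log(0.2))) / (1 + 4),
               tolerance = 1e-12)
  all3 <- cumulative_degree_fit(c(3L, 3L, 3L))
  expect_true(is.nan(all3$beta))
  expect_match(attr(all3$beta, "reason"), "degree 3")
})

test_that("beta is recovered from large sampled degree sets", {
  set.seed(11)
  for (b in c(0.8, 1.2)) {
    deg <- 3L + rgeom(1e5, 1 - exp(-b))
    expect_lt(abs(cumulative_degree_fit(deg)$beta / b - 1), 0.10)
  }
})

test_that("regressions match closed forms and reject degenerate input", {
  lr <- linear_regression(c(0, 1, 2), c(0, 2, 4))
  expect_equal(lr$slope, 2, tolerance = 1e-12)
  expect_equal(lr$intercept, 0, tolerance = 1e-12)
  expect_equal(lr$r, 1, tolerance = 1e-12)
  pl <- power_law_fit(1:10, 2 * (1:10)^1.5)
  expect_equal(pl$exponent, 1.5, tolerance = 1e-12)
  expect_equal(pl$prefactor, 2, tolerance = 1e-12)
  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(linear_regression(1:2, 1:2), "3 finite")
})

test_that("smoothed histograms are normalized and reduce to raw at sigma 0", {
  set.seed(2)
  h <- smoothed_histogram(rnorm(500), seq(-4, 4, by = 0.25))
  expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
  expect_true(all(h$frequency >= 0))
  h0 <- smoothed_histogram(c(1.1, 1.2, 2.5), c(0, 1, 2, 3), sigma_bins = 0)
  expect_equal(h0$frequency, c(0, 2 / 3, 1 / 3))
  # all mass in one bin smooths to a symmetric bump around it
  h1 <- smoothed_histogram(rep(5.5, 10), 0:11, sigma_bins = 1)
  expect_equal(which.max(h1$frequency), 6)
  expect_equal(h1$frequency[5], h1$frequency[7], tolerance = 1e-9)
  expect_error(smoothed_histogram(numeric(), 0:2), "finite")
})

test_that("variability decomposition matches its hand-computed oracle", {
  vs <- variability_summary(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(vs$inter, 1)
  expect_equal(vs$intra, 1)
  same <- variability_summary(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$inter, 0)
  expect_error(variability_summary(list(c(1, 2))), "2 samples")
  expect_error(variability_summary(list(1, c(1, 2))), "2 values")
})

test_that("group comparisons match Student's closed forms", {
  gp <- group_comparison(c(1, 2, 3), c(2, 2.5, 4.5), paired = TRUE)
  expect_equal(abs(gp$t), 1 / (0.5 / sqrt(3)), tolerance = 1e-10)
  expect_equal(gp$df, 2)
  a <- c(4.1, 5.2, 6.3, 5.5)
  b <- c(3.0, 3.8, 4.4)
  sp2 <- (3 * var(a) + 2 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  gi <- group_comparison(a, b)
  expect_equal(gi$t, t_hand, tolerance = 1e-10)
  expect_equal(gi$p, 2 * pt(-abs(t_hand), 5), tolerance = 1e-10)
  same <- group_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(group_comparison(1, c(1, 2)), "n >= 2")
  expect_error(group_comparison(c(1, 2), c(1, 2, 3), paired = TRUE),
               "equal lengths")
})
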