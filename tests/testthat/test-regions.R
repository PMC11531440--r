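test_that("skeleton z-projection counts and locates voxels", {
  arr <- array(FALSE, c(6, 5, 7))
  expect_true(all(project_skeleton_z(arr) == 0))
  arr[3, 2, 5] <- TRUE
  pr <- project_skeleton_z(arr)
  expect_equal(sum(pr > 0), 1)
  expect_equal(pr[3, 2], 1)
  arr2 <- array(FALSE, c(4, 4, 20))
  arr2[2, 3, ] <- TRUE
  expect_equal(project_skeleton_z(arr2, "count")[2, 3], 20)
  expect_equal(project_skeleton_z(arr2, "max")[2, 3], 1)
})

test_that("area fractions sum to one and respect the mask", {
  cellh <- 400^(1 / 3)
  g <- lcn_graph()
  m <- suppressWarnings(compute_subvolume_maps(g, rep(4 * cellh, 3)))
  all_ord <- region_mask2d(matrix(1L, 40, 40), rep(4 * cellh / 40, 2))
  rs <- region_statistics(m, all_ord)
  expect_equal(unname(rs$area_fraction["ordered"]), 1)
  expect_equal(rs$n_cells[["unordered"]], 0)
  half <- region_mask2d(cbind(matrix(1L, 40, 20), matrix(2L, 40, 20)),
                        rep(4 * cellh / 40, 2))
  rs2 <- region_statistics(m, half)
  expect_equal(sum(rs2$area_fraction), 1, tolerance = 1e-9)
  expect_equal(unname(rs2$area_fraction["ordered"]), 0.5, tolerance = 1 / 40)
})

test_that("ties in the footprint majority go to the unordered class", {
  cellh <- 400^(1 / 3)
  g <- lcn_graph(data.frame(id = 1L, x_um = cellh / 2, y_um = cellh / 2,
                            z_um = cellh / 2, kind = "junction"))
  m <- compute_subvolume_maps(g, rep(cellh, 3))
  tie <- region_mask2d(matrix(c(1L, 2L), 2, 2), rep(cellh / 2, 2))
  rs <- region_statistics(m, tie)
  expect_equal(rs$n_cells[["unordered"]], 1)
})

test_that("misaligned masks are rejected", {
  cellh <- 400^(1 / 3)
  g <- lcn_graph()
  m <- suppressWarnings(compute_subvolume_maps(g, rep(4 * cellh, 3)))
  small <- region_mask2d(matrix(1L, 4, 4), c(1, 1))
  expect_error(region_statistics(m, small), "cover")
})

test_that("phantom region statistics recover the unordered band", {
  tr <- small_truth()
  mask <- truth_region_mask(tr)
  frac_un <- mean(mask$labels == 2L)
  expect_lt(abs(frac_un - 0.3), 0.02)
  m <- compute_subvolume_maps(tr$graph, rep(30, 3))
  rs <- region_statistics(m, mask)
  expect_lt(abs(rs$area_fraction[["unordered"]] - 0.3), 0.02)
  expect_lt(mean(rs$per_region$unordered$can_dn),
            mean(rs$per_region$ordered$can_dn))
})

test_that("region assignment is independent of label enumeration order", {
  tr <- small_truth()
  mask <- truth_region_mask(tr)
  m <- compute_subvolume_maps(tr$graph, rep(30, 3))
  rs1 <- region_statistics(m, mask)
  rs2 <- region_statistics(m, mask)
  expect_identical(rs1$per_region, rs2$per_region)
})

test_that("orientation coherence is high for combed, low for isotropic", {
  set.seed(3)
  n <- 80
  combed <- matrix(0, n, n)
  combed[, seq(2, n, by = 4)] <- 1 # parallel lines
  iso <- matrix(runif(n * n) < 0.25, n, n) * 1
  ch_c <- orientation_coherence(combed)
  ch_i <- orientation_coherence(iso)
  inner <- 20:60
  expect_gt(mean(ch_c[inner, inner]), mean(ch_i[inner, inner]))
})
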