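test_that("reference gray levels map to the element backscatter yields", {
  cal <- build_calibration(gl_carbon = 25, gl_aluminum = 225)
  expect_equal(gray_to_eta(cal, 25), backscatter_coefficient(6))
  expect_equal(gray_to_eta(cal, 225), backscatter_coefficient(13))
  # midway gray -> midway eta (linearity)
  expect_equal(gray_to_eta(cal, 125),
               (backscatter_coefficient(6) + backscatter_coefficient(13)) / 2,
               tolerance = 1e-12)
  # polynomial agrees with an independent Horner evaluation
  horner <- function(z) ((8.3e-7 * z - 1.86e-4) * z + 0.016) * z - 0.0254
  expect_equal(backscatter_coefficient(6), horner(6), tolerance = 1e-12)
  expect_equal(backscatter_coefficient(13), horner(13), tolerance = 1e-12)
})

test_that("calibration is affine and increasing in gray level", {
  cal <- build_calibration()
  img <- matrix(as.integer(0:255), 16)
  ca <- apply_calibration(img, cal)$wt_pct_ca
  d <- diff(sort(unique(as.numeric(ca))))
  expect_true(all(d > 0))
  # shifting gray by delta shifts calcium by c1 * delta exactly
  ca2 <- apply_calibration(img + 0L, cal)$wt_pct_ca
  expect_equal(apply_calibration(matrix(10L), cal)$wt_pct_ca[1] -
                 apply_calibration(matrix(7L), cal)$wt_pct_ca[1],
               3 * cal$c1, tolerance = 1e-12)
  # carbon anchor at 0 wt%
  expect_equal(apply_calibration(matrix(25L), cal)$wt_pct_ca[1], 0,
               tolerance = 1e-12)
  expect_error(build_calibration(anchors = list(c(10, 0), c(10, 5))),
               "degenerate")
  expect_error(apply_calibration(matrix(300L), cal), "0..255")
})

test_that("qBEI phantoms round-trip through the calibration", {
  p <- generator_params(domain_size_um = c(20, 20, 10),
                        lacuna_number_density = 0, target_node_density = 0,
                        target_can_density = 0,
                        interface_plane = list(axis = "x", position_um = 12),
                        seed = 4)
  tr <- generate_ground_truth(p)
  cal <- build_calibration()
  ph <- generate_qbei_phantom(tr, low_ca = 18, high_ca = 27, curve = cal)
  expect_setequal(unique(as.numeric(ph$gl)), range(ph$gl))
  cam <- apply_calibration(ph$gl, cal)
  # recovered within one gray-level quantum on each side of the interface
  expect_lt(max(abs(cam$wt_pct_ca - ph$ca_true)), cal$c1)
  # interface position within one pixel of x = 12
  lowcol <- ph$gl[, 1] == min(ph$gl)
  x_edge <- max(which(lowcol)) * tr$params$voxel_spacing_um[1]
  expect_lt(abs(x_edge - 12), 2 * tr$params$voxel_spacing_um[1])
})

test_that("a truth without interface gives a single-valued map", {
  p <- generator_params(domain_size_um = c(10, 10, 10),
                        lacuna_number_density = 0, target_node_density = 0,
                        target_can_density = 0, seed = 5)
  tr <- generate_ground_truth(p)
  ph <- generate_qbei_phantom(tr, low_ca = 20, high_ca = 30)
  expect_equal(length(unique(as.numeric(ph$gl))), 1)
  expect_true(all(ph$ca_true == 20))
})
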