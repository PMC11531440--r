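test_that("zero densities give an empty network", {
  p <- generator_params(lacuna_number_density = 0, target_node_density = 0,
                        target_can_density = 0, seed = 1)
  tr <- generate_ground_truth(p)
  expect_equal(nrow(tr$graph$nodes), 0)
  expect_equal(nrow(tr$graph$edges), 0)
  expect_equal(total_length(tr$graph), 0)
  img <- rasterize(tr, p)
  expect_true(all(img$data == 0))
})

test_that("junction count follows the Poisson sampling oracle", {
  tr <- generate_ground_truth(generator_params(domain_size_um = c(60, 60, 60),
                                               lacuna_number_density = 0,
                                               seed = 2))
  lambda <- 0.05 * 60^3
  n_j <- sum(tr$graph$nodes$kind == "junction")
  expect_lt(abs(n_j - lambda), 3 * sqrt(lambda))
})

test_that("implied mean edge length follows the density arithmetic", {
  # printed parameter scales: Can.Dn 0.21, Nd.Nr 0.05, Nd.Dg 3.16
  expect_equal(implied_mean_edge_length(0.21, 0.05, 3.16),
               0.21 / (0.05 * 3.16 / 2), tolerance = 1e-12)
  expect_equal(round(implied_mean_edge_length(0.21, 0.05, 3.16), 2), 2.66)
  tr <- small_truth()
  p <- tr$params
  expect_equal(tr$metadata$implied_mean_edge_length_um,
               implied_mean_edge_length(p$target_can_density,
                                        p$target_node_density,
                                        3 + 1 / expm1(p$degree_tail_beta)),
               tolerance = 1e-12)
})

test_that("realized densities hit their targets within 10%", {
  tr <- generate_ground_truth(generator_params(domain_size_um = c(50, 50, 50),
                                               seed = 31))
  r <- tr$realized$overall
  expect_lt(abs(r$can_dn / 0.21 - 1), 0.10)
  expect_lt(abs(r$nd_nr / 0.05 - 1), 0.10)
})

test_that("generation is bit-reproducible for a fixed seed", {
  p <- generator_params(domain_size_um = c(20, 20, 20), seed = 99)
  t1 <- generate_ground_truth(p)
  t2 <- generate_ground_truth(p)
  expect_identical(t1$graph$nodes, t2$graph$nodes)
  expect_identical(t1$graph$edges, t2$graph$edges)
  expect_identical(t1$graph$paths, t2$graph$paths)
  i1 <- degrade(rasterize(t1, p), p)
  i2 <- degrade(rasterize(t2, p), p)
  expect_identical(i1$data, i2$data)
})

test_that("ellipsoid rasterization reproduces the analytic volume", {
  sp <- c(0.379, 0.379, 0.340)
  dims <- as.integer(ceiling(c(24, 16, 12) / sp))
  img <- lcntools:::cpp_raster_ellipsoids(matrix(c(12, 8, 6), 1),
                                          matrix(c(9, 5, 3), 1), list(diag(3)),
                                          dims, sp, numeric(prod(dims)))
  vol <- sum(img) * prod(sp) # coverage-fraction sum integrates the volume
  expect_lt(abs(vol / (4 / 3 * pi * 9 * 5 * 3) - 1), 0.05)
})

test_that("tube rasterization reproduces the analytic cylinder volume", {
  tube <- make_tube_stack(length_um = 10, radius_um = 0.15)
  vol <- sum(tube$stack$data) * prod(tube$spacing)
  analytic <- pi * 0.15^2 * 10
  expect_lt(abs(vol / analytic - 1), 0.5)
  # foreground voxels stay within a voxel of the analytic cylinder
  idx <- which(tube$stack$data > 0, arr.ind = TRUE)
  pos <- (idx - 0.5) * matrix(tube$spacing, nrow(idx), 3, byrow = TRUE)
  r_off <- sqrt((pos[, 2] - 4)^2 + (pos[, 3] - 4)^2)
  expect_lt(max(r_off), 0.15 + max(tube$spacing))
})

test_that("degrade is the identity without psf, noise and gradient", {
  ph <- mini_phantom()
  img <- rasterize(ph$truth, ph$params)
  p0 <- ph$params
  p0$psf_sigma_um <- c(0, 0, 0)
  p0$noise_sd <- 0
  p0$background_gradient <- 0
  expect_identical(degrade(img, p0)$data, img$data)
})

test_that("degrade noise has the requested standard deviation", {
  p <- generator_params(noise_sd = 0.05, psf_sigma_um = c(0, 0, 0),
                        background_gradient = 0, seed = 3)
  zero <- image_stack(array(0, c(100, 100, 100)))
  out <- degrade(zero, p)
  expect_lt(abs(sd(out$data) / 0.05 - 1), 0.05)
  expect_identical(out$data, degrade(zero, p)$data) # seeded: bit-identical
})

test_that("the true degree tail matches the configured exponential decay", {
  tr <- generate_ground_truth(generator_params(domain_size_um = c(60, 60, 60),
                                               lacuna_number_density = 0,
                                               seed = 4))
  fit <- cumulative_degree_fit(tr$graph)
  expect_equal(fit$cumulative[1], 1)
  expect_true(all(diff(fit$cumulative) <= 0))
  expect_lt(abs(fit$beta / 1.2 - 1), 0.10)
})

test_that("ordered region is denser and aligned, unordered is isotropic", {
  tr <- small_truth()
  expect_gt(tr$realized$ordered$can_dn, tr$realized$unordered$can_dn)
  # alignment: chord direction of ordered-region edges vs x axis
  g <- tr$graph
  cosx <- vapply(g$paths, function(p) {
    d <- p[nrow(p), ] - p[1, ]
    abs(d[1]) / sqrt(sum(d^2))
  }, numeric(1))
  mids <- t(vapply(g$paths, function(p) p[ceiling(nrow(p) / 2), ], numeric(3)))
  unord <- mids[, 2] < tr$params$unordered_fraction * 30
  # preferential (not strict) alignment: clearly above the isotropic region
  expect_gt(mean(cosx[!unord]), mean(cosx[unord]) + 0.08)
  expect_lt(mean(cosx[unord]), 0.65)          # isotropic mean |cos| = 0.5
})

test_that("no true edge crosses a configured interface plane", {
  p <- generator_params(domain_size_um = c(30, 30, 30),
                        interface_plane = list(axis = "x", position_um = 15),
                        lacuna_number_density = 0, seed = 8)
  tr <- generate_ground_truth(p)
  sides <- vapply(tr$graph$paths, function(pp)
    if (all(pp[, 1] > 15)) 1L else if (all(pp[, 1] < 15)) -1L else 0L,
    integer(1))
  expect_true(all(sides != 0L))
  expect_true(any(sides == 1L) && any(sides == -1L))
})

test_that("cohorts have the study layout and paired limbs share targets", {
  co <- generate_cohort(n_per_group = 2, seed = 5,
                        base_params = generator_params(
                          domain_size_um = c(20, 20, 20),
                          lacuna_number_density = 0))
  expect_length(co, 2 * 2 * 2) # 2 strains x 2 animals x 2 limbs
  lab <- cohort_labels(co)
  expect_setequal(unique(lab$strain), c("balbc_like", "c57_like"))
  for (st in unique(lab$strain)) for (an in unique(lab$animal)) {
    pair <- co[vapply(co, function(s)
      s$strain == st && s$animal == an, logical(1))]
    expect_equal(pair[[1]]$truth$params$target_can_density,
                 pair[[2]]$truth$params$target_can_density)
    expect_false(pair[[1]]$seed == pair[[2]]$seed)
  }
})

test_that("the denser strain preset realizes a denser network", {
  co <- generate_cohort(n_per_group = 3, seed = 6,
                        base_params = generator_params(
                          domain_size_um = c(25, 25, 25),
                          lacuna_number_density = 0))
  lab <- cohort_labels(co)
  expect_gt(mean(lab$can_dn[lab$strain == "c57_like"]),
            mean(lab$can_dn[lab$strain == "balbc_like"]))
})

test_that("lacuna shape population matches its construction", {
  set.seed(1)
  sh <- sample_lacuna_shapes(500, generator_params())
  expect_true(all(sh$a_um >= sh$b_um & sh$b_um >= sh$c_um))
  expect_true(all(abs(sh$volume_um3 - 4 / 3 * pi * sh$a_um * sh$b_um * sh$c_um)
                  < 1e-9))
  expect_true(all(sh$degree == round(sh$area_um2 / 5.75)))
  expect_true(all(sh$stretch > 0.3 & sh$stretch < 0.8))
  expect_true(all(sh$oblateness < 0)) # rod-like by construction
})
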