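test_that("water-equivalent depth scales geometric depth by mean density", {
  # direct evaluation of the depth-scaling rule on constructed ray paths
  ray <- structure(list(geom_depth = 50, densities = rep(1, 40)), class = "ray_path")
  expect_equal(water_equivalent_depth(ray), 50)
  ray$densities <- rep(0.5, 40)
  ray$geom_depth <- 80
  expect_equal(water_equivalent_depth(ray), 40)
  # half the path at density 1, half at 0.25: mean 0.625, depth 40 -> 25
  ray$densities <- c(rep(1, 20), rep(0.25, 20))
  ray$geom_depth <- 40
  expect_equal(water_equivalent_depth(ray), 25)
})

test_that("traced rays through phantoms reproduce the closed-form depths", {
  ph <- make_phantom("homogeneous_water", lateral = 50, thickness = 120, spacing = 5)
  expect_equal(water_equivalent_depth(c(0, 0, 50), ph), 50, tolerance = 0.02)
  ph2 <- ph
  ph2$density[] <- 0.5
  expect_equal(water_equivalent_depth(c(0, 0, 80), ph2), 40, tolerance = 0.02)
  # layered phantom: 20 mm water over 0.25-density material, target at 40 mm
  ph3 <- ph
  ph3$density[, , ph$z > 20] <- 0.25
  expect_equal(water_equivalent_depth(c(0, 0, 40), ph3), 25, tolerance = 0.03 * 25)
  # a ray that misses the contour errors
  cyl <- make_phantom("cylinder", radius = 30, lateral = 100, spacing = 5)
  expect_error(ray_path(cyl, c(90, 0, 55)), "misses")
})

test_that("point reconstruction applies the TPR ratio and inverse square law", {
  beam <- make_beam_model()
  # identical depths and distances: identity
  expect_equal(reconstruct_point(2.5, 100, 100, 1000, 1000, beam), 2.5)
  # doubling the distance quarters the dose
  expect_equal(reconstruct_point(8, 100, 100, 500, 1000, beam), 2)
  # exponential TPR closed form: Z_Det 100 -> Z_CT 50 at equal distances
  mu <- 0.005
  be <- make_beam_model(pdd_table = cbind(0:400, exp(-mu * (0:400))), ssd = Inf)
  expect_equal(reconstruct_point(1, 100, 50, 1000, 1000, be), exp(0.25),
               tolerance = 1e-10)
  expect_error(reconstruct_point(1, -5, 50, 1000, 1000, beam), "depths")
})

test_that("uniform map on water with flat TPR reconstructs pure inverse square", {
  ph <- make_phantom("homogeneous_water", lateral = 140, thickness = 200,
                     spacing = 5, det_depth = 97.5)
  flat <- make_beam_model(pdd_table = cbind(0:400, 1), ssd = Inf)
  a <- build_array("d729")
  uni <- dose_grid(matrix(2, 321, 321), origin = c(-160, -160))
  m <- sample_dose(uni, a)
  vol <- reconstruct_volume(m, ph, flat)
  # central-axis profile: D(z) = 2 * (a_det / a_z)^2, focus at z = -902.5
  iz <- which(ph$x == 2.5)  # nearest on-axis voxel column
  fz <- ph$focus[3]
  for (l in c(3, 15, 30)) {
    a_det <- sqrt(2.5^2 + 2.5^2 + (97.5 - fz)^2)
    a_ct <- sqrt(2.5^2 + 2.5^2 + (ph$z[l] - fz)^2) *
      ((97.5 - fz) / (ph$z[l] - fz)) * ((ph$z[l] - fz) / (97.5 - fz))
    analytic <- 2 * ((97.5 - fz) / (ph$z[l] - fz))^2
    expect_equal(vol$values[iz, iz, l], analytic, tolerance = 0.01)
  }
})

test_that("reconstruction at the measurement plane returns the measured dose", {
  # homogeneous-water identity: the voxel layer holding the detector plane
  # reproduces the measured values at the sample positions exactly
  ph <- make_phantom("homogeneous_water", lateral = 140, thickness = 200,
                     spacing = 5, det_depth = 97.5)
  beam <- make_beam_model()
  g <- generate_vmat_dosemap(rectangular_field(c(100, 100)))
  m <- sample_dose(g, build_array("d729"))
  vol <- reconstruct_volume(m, ph, beam)
  l <- which(ph$z == 97.5)
  # voxel centres at +-2.5, ... do not coincide with chamber centres (0, 10, ...);
  # compare against linear interpolation of the map at the voxel positions
  probe <- expand.grid(x = ph$x[abs(ph$x) < 100], y = ph$y[abs(ph$y) < 100])
  got <- vol$values[cbind(match(probe$x, ph$x), match(probe$y, ph$y),
                          rep(l, nrow(probe)))]
  expect_equal(got, interp_map(m, probe$x, probe$y), tolerance = 1e-9)
})

test_that("reconstruction is linear in the measured dose", {
  ph <- make_phantom("homogeneous_water", lateral = 90, thickness = 150,
                     spacing = 5, det_depth = 97.5)
  beam <- make_beam_model()
  g <- generate_vmat_dosemap(rectangular_field(c(80, 80)))
  m <- sample_dose(g, build_array("d729"))
  m2 <- m
  m2$dose <- 3 * m$dose
  v1 <- reconstruct_volume(m, ph, beam)
  v2 <- reconstruct_volume(m2, ph, beam)
  expect_equal(v2$values, 3 * v1$values, tolerance = 1e-12)
})

test_that("an upstream low-density slab increases downstream reconstructed dose", {
  beam <- make_beam_model()
  water <- make_phantom("homogeneous_water", lateral = 90, thickness = 200,
                        spacing = 5, det_depth = 97.5)
  thorax <- make_phantom("thorax_like", lateral = 90, thickness = 200,
                         spacing = 5, det_depth = 97.5,
                         insert_z = c(110, 150), insert_density = 0.25)
  uni <- dose_grid(matrix(1, 321, 321), origin = c(-160, -160))
  m <- sample_dose(uni, build_array("d729"))
  vw <- reconstruct_volume(m, water, beam)
  vt <- reconstruct_volume(m, thorax, beam)
  iz <- which(water$x == 2.5)
  deep <- which(water$z > 160)  # downstream of the slab
  expect_true(all(vt$values[iz, iz, deep] > vw$values[iz, iz, deep]))
})

test_that("cumulative DVH and D50 have the closed-form limits", {
  uni <- array(4.2, dim = c(6, 6, 3))
  dv <- compute_dvh(uni)
  expect_equal(dv$d50, 4.2)
  expect_true(all(diff(dv$curve$volume_fraction) <= 0))
  # linear gradient spanning [0, Dmax] uniformly: D50 = Dmax / 2
  n <- 40000
  grad <- array(seq(0, 10, length.out = n), dim = c(n, 1, 1))
  expect_equal(compute_dvh(grad)$d50, 5, tolerance = 0.01)
  # identical reconstruction vs reference: percent difference 0
  dv2 <- compute_dvh(uni, reference = 4.2)
  expect_equal(dv2$d50_percent_diff, 0)
  expect_error(compute_dvh(uni, mask = array(FALSE, dim(uni))), "empty")
})

test_that("denser sampling recovers D50 at least as well as sparse sampling", {
  # dense (full 5 mm lattice) vs sparse (d729 SA) D50 against the analytic
  # reference from the underlying planar dose, over seeded replicates
  ph <- make_phantom("homogeneous_water", lateral = 140, thickness = 160,
                     spacing = 5, det_depth = 97.5)
  beam <- make_beam_model()
  a729 <- build_array("d729")
  mask <- array(FALSE, dim = dim(ph$density))
  mask[abs(ph$x) <= 50, abs(ph$y) <= 50, ph$z >= 60 & ph$z <= 140] <- TRUE
  gx <- seq(-130, 130, by = 5)
  wins <- 0L
  n_rep <- 5L
  for (s in seq_len(n_rep)) {
    set.seed(100 + s)
    g <- generate_vmat_dosemap(random_field_spec())
    dense <- vmatqa:::measured_map(
      rep(gx, times = length(gx)), rep(gx, each = length(gx)),
      interp_grid(g, rep(gx, times = length(gx)), rep(gx, each = length(gx)))
    )
    ref_d50 <- compute_dvh(reconstruct_volume(dense, ph, beam), mask)$d50
    # the analytic reference: reconstruction from a very dense sampling of the
    # same planar dose; dense vs sparse error is measured against it
    sparse <- sample_dose(g, a729)
    half <- vmatqa:::measured_map(
      rep(gx, times = length(gx)), rep(gx, each = length(gx)),
      interp_map(sparse, rep(gx, times = length(gx)), rep(gx, each = length(gx)))
    )
    d50_sparse <- compute_dvh(reconstruct_volume(sparse, ph, beam), mask)$d50
    err_sparse <- abs(d50_sparse - ref_d50)
    # a 1500-like checkerboard of the truth: denser than d729
    m1500 <- sample_dose(g, build_array("d1500"))
    d50_1500 <- compute_dvh(reconstruct_volume(m1500, ph, beam), mask)$d50
    if (abs(d50_1500 - ref_d50) <= err_sparse + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.8 * n_rep))
})

test_that("reconstructed volumes serialise as stacked plain-text grids", {
  ph <- make_phantom("homogeneous_water", lateral = 30, thickness = 30, spacing = 10,
                     det_depth = 15)
  beam <- make_beam_model()
  uni <- dose_grid(matrix(1, 321, 321), origin = c(-160, -160))
  # small custom map inside the tiny phantom
  m <- vmatqa:::measured_map(rep(c(-20, 0, 20), 3), rep(c(-20, 0, 20), each = 3), rep(1, 9))
  vol <- reconstruct_volume(m, ph, beam)
  prefix <- file.path(withr::local_tempdir(), "vol")
  paths <- write_reconstructed_dose(vol, prefix)
  expect_length(paths, length(ph$z))
  g1 <- read_dose_grid(paths[1])
  expect_identical(g1$values, vol$values[, , 1])
})
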