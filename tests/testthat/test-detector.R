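test_that("array geometries match the commercial specifications", {
  a729 <- build_array("d729")
  a1500 <- build_array("d1500")
  expect_equal(n_chambers(a729), 729L)
  expect_equal(n_chambers(a1500), 1405L)
  expect_error(build_array("d1000"))
  # d729: 10 mm pitch, 5 mm edge-to-edge gaps over 27 x 27 cm^2
  expect_equal(sort(unique(a729$x)), seq(-130, 130, by = 10))
  expect_equal(a729$aperture, 5)
  # d1500 nearest-neighbour (diagonal) centre distance is 7.07 mm
  i <- which(a1500$x == 0 & a1500$y == 0)
  d <- sqrt((a1500$x - 0)^2 + (a1500$y - 0)^2)
  expect_equal(min(d[-i]), sqrt(50), tolerance = 1e-12)
  expect_equal(round(min(d[-i]), 2), 7.07)
})

test_that("chamber sampling averages the dose over the square aperture", {
  a <- build_array("d729")
  uni <- dose_grid(matrix(7.5, 321, 321), origin = c(-160, -160))
  m <- sample_dose(uni, a)
  expect_equal(m$dose, rep(7.5, 729))
  # linear ramp: aperture midpoint symmetry gives the centre value
  xs <- seq(-160, 160)
  ramp <- dose_grid(outer(xs, rep(1, 321)) * 0.01 + 2, origin = c(-160, -160))
  mr <- sample_dose(ramp, a)
  expect_equal(mr$dose, 0.01 * mr$x + 2, tolerance = 1e-12)
  # step edge bisecting the 5 mm aperture reads (high + low) / 2
  step_vals <- matrix(1, 321, 321); step_vals[xs >= 0, ] <- 3
  stepg <- dose_grid(step_vals, origin = c(-160, -160))
  ms <- sample_dose(stepg, a)
  centre <- ms$dose[ms$x == 0 & ms$y == 0]
  expect_equal(centre, 2, tolerance = 0.2)  # quadrature tolerance at 1 mm pixels
})

test_that("sampling is linear in the dose distribution", {
  set.seed(21)
  a <- build_array("d1500")
  A <- smooth_random_grid(n = 130, spacing = 2.5)
  B <- smooth_random_grid(n = 130, spacing = 2.5)
  lin <- dose_grid(2 * A$values + 3 * B$values, origin = A$origin, spacing = A$spacing)
  m <- sample_dose(lin, a)
  expect_equal(m$dose, 2 * sample_dose(A, a)$dose + 3 * sample_dose(B, a)$dose,
               tolerance = 1e-12)
})

test_that("apertures falling off the dose grid are reported by chamber", {
  a <- build_array("d729")
  small <- dose_grid(matrix(1, 101, 101), origin = c(-50, -50))
  expect_error(sample_dose(small, a), "chamber")
})

test_that("coalescing the isocentre and +5 mm acquisitions doubles the points", {
  f <- rectangular_field(c(100, 100))
  g <- generate_vmat_dosemap(f)
  a <- build_array("d729")
  iso <- sample_dose(g, a)
  sh <- sample_dose(g, a, c(0, 5))
  co <- coalesce(iso, sh)
  expect_equal(length(co$x), 1458L)
  expect_identical(attr(co, "overlap")$n_merged, 0L)
  # both parents' values survive unchanged
  expect_true(all(iso$dose %in% co$dose))
  expect_true(all(sh$dose %in% co$dose))
})

test_that("coalescence merges duplicates, is idempotent and checks overlap", {
  f <- rectangular_field(c(100, 100))
  g <- generate_vmat_dosemap(f)
  a <- build_array("d729")
  iso <- sample_dose(g, a)
  # coalescing a map with itself at zero shift reproduces the map
  self <- coalesce(iso, iso, tolerance = 1)
  expect_equal(length(self$x), length(iso$x))
  expect_equal(self$dose[order(self$x, self$y)],
               iso$dose[order(iso$x, iso$y)])
  expect_equal(attr(self, "overlap")$max_discrepancy, 0)
  # two samplings of the same static dose always coalesce at any tolerance > 0
  expect_no_error(coalesce(iso, sample_dose(g, a), tolerance = 1e-9))
  # discrepant overlapping doses fail with the max discrepancy attached
  bad <- iso; bad$dose <- bad$dose + 0.5
  err <- tryCatch(coalesce(iso, bad, tolerance = 0.1), coalescence_error = identity)
  expect_s3_class(err, "coalescence_error")
  expect_equal(err$max_discrepancy, 0.5, tolerance = 1e-12)
  # mismatched array models are rejected outright
  other <- sample_dose(g, build_array("d1500"))
  expect_error(coalesce(iso, other), "different array models")
})

test_that("sampling frequencies match the published per-direction values", {
  a1500 <- build_array("d1500")
  a729 <- build_array("d729")
  expect_equal(sampling_frequency(a1500, "row"), 0.1)
  expect_equal(sampling_frequency(a1500, "row", coalesced = TRUE), 0.2)
  expect_equal(round(sampling_frequency(a1500, "diagonal"), 2), 0.14)
  expect_equal(sampling_frequency(a729, "row"), 0.1)
  expect_equal(sampling_frequency(a729, "column", coalesced = TRUE), 0.2)
  # frequency computed from an actual coalesced map agrees
  g <- generate_vmat_dosemap(rectangular_field(c(100, 100)))
  co <- coalesce(sample_dose(g, a729), sample_dose(g, a729, c(0, 5)))
  expect_equal(sampling_frequency(co, "column"), 0.2)
})

test_that("geometric fill factors: linear 0.5 for d729; coalescence raises both", {
  a729 <- build_array("d729")
  a1500 <- build_array("d1500")
  expect_equal(fill_factor(a729, "linear"), 0.5)
  expect_equal(fill_factor(a729, "areal"), 0.25)
  expect_gt(fill_factor(a1500, "linear", coalesced = TRUE),
            fill_factor(a1500, "linear"))
  expect_true(all(c(fill_factor(a1500, "areal"), fill_factor(a729, "areal", TRUE)) <= 1))
})

test_that("a 2.5 mm leaf aligned with the inter-row gap is missed by SA and seen after coalescence", {
  # leaf strip spanning y in [5, 7.5): between the y = 0 and y = 10 chamber rows
  mlc <- hdmlc_geometry()
  pair <- which(mlc$lower == 5 & mlc$widths == 2.5)
  f <- single_pair_field(pair, x_open = c(-50, 50), penumbra_sigma = 0)
  g <- generate_vmat_dosemap(f)
  plateau <- max(g$values)
  a <- build_array("d729")
  iso <- sample_dose(g, a)
  expect_lt(max(iso$dose), 0.05 * plateau)
  co <- coalesce(iso, sample_dose(g, a, c(0, 5)))
  expect_gt(max(co$dose), 0.5 * plateau)
})

test_that("measured maps round-trip through CSV", {
  g <- generate_vmat_dosemap(rectangular_field(c(80, 80)))
  m <- sample_dose(g, build_array("d1500"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measured_map(m, path)
  m2 <- read_measured_map(path)
  expect_equal(m2$x, m$x)
  expect_equal(m2$dose, m$dose)
})

test_that("lattice interpolation of a checkerboard map is linear-exact", {
  # checkerboard samples of a planar ramp interpolate the ramp exactly
  xs <- seq(-160, 160)
  ramp <- dose_grid(outer(xs * 0.02, xs * 0.01, "+") + 10, origin = c(-160, -160))
  m <- sample_dose(ramp, build_array("d1500"))
  q <- interp_map(m, c(0, 3, -12.5), c(0, 4, 7.5))
  expect_equal(q, 0.02 * c(0, 3, -12.5) + 0.01 * c(0, 4, 7.5) + 10, tolerance = 1e-10)
})
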