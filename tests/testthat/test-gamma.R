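test_that("identical distributions give gamma 0 everywhere above threshold", {
  set.seed(31)
  g <- smooth_random_grid(n = 20, spacing = 2.5)
  res <- gamma_map(g, g, gamma_criteria(3, 2, "global"))
  in_mask <- res$points$in_mask
  expect_true(all(res$points$gamma[in_mask] == 0))
  expect_equal(pass_rate(res), 100)
  # below-threshold points carry no gamma
  expect_true(all(is.na(res$points$gamma[!in_mask])))
})

test_that("a pure 3% dose offset against a uniform evaluated map gives gamma 1", {
  # single reference point D = 100 at the origin, evaluated uniform 103:
  # the dose axis alone determines gamma = 3 / (3% of 100) = 1
  ref <- data.frame(x = 0, y = 0, dose = 100)
  ev <- dose_grid(matrix(103, 41, 41), origin = c(-20, -20))
  res <- gamma_map(ref, ev, gamma_criteria(3, 2, "global"))
  expect_equal(res$points$gamma, 1, tolerance = 1e-9)
})

test_that("implementation matches the exhaustive brute-force oracle on random maps", {
  set.seed(42)
  for (rep in 1:3) {
    ref <- smooth_random_grid(n = 20, spacing = 2.5)
    ev_vals <- ref$values * (1 + stats::rnorm(1, 0, 0.02)) +
      matrix(stats::rnorm(400, 0, 1.5), 20, 20)
    ev <- dose_grid(pmax(ev_vals, 0), origin = ref$origin, spacing = ref$spacing)
    cr <- gamma_criteria(3, 2, "global")
    # same sub-grid density as the oracle: the implementation searches the
    # oracle's candidate lattice plus the exact reference position, so it can
    # only be equal or (marginally) smaller
    res <- gamma_map(ref, ev, cr, step = cr$dta / 20)
    oracle <- gamma_oracle(ref, ev, cr)
    got <- matrix(res$points$gamma, 20, 20)
    expect_true(all(got <= oracle + 1e-9, na.rm = TRUE))
    expect_lt(max(abs(got - oracle), na.rm = TRUE), 0.05)
    expect_equal(is.na(got), is.na(oracle))
  }
})

test_that("pass rate counts gamma <= 1 among masked points", {
  # construct a result with exactly half the masked points failing
  pts <- data.frame(x = 1:8, y = 0, ref_dose = 50,
                    gamma = c(0, 0, 0, 0, 2, 2, 2, 2),
                    pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    in_mask = TRUE)
  res <- structure(list(points = pts, criteria = gamma_criteria(),
                        norm_dose = 50, n_undefined = 0L),
                   class = "gamma_result")
  expect_equal(pass_rate(res), 50)
  # recount oracle on a computed case
  set.seed(43)
  ref <- smooth_random_grid(20, 2.5)
  ev <- dose_grid(ref$values + matrix(stats::rnorm(400, 0, 2), 20, 20) + 3,
                  origin = ref$origin, spacing = ref$spacing)
  res2 <- gamma_map(ref, ev, gamma_criteria(2, 1, "global"))
  g <- res2$points$gamma[res2$points$in_mask]
  expect_equal(pass_rate(res2), 100 * sum(g <= 1) / length(g))
})

test_that("loosening criteria never decreases the pass rate", {
  set.seed(44)
  ref <- smooth_random_grid(25, 2.5)
  ev <- dose_grid(pmax(ref$values * 1.015 + matrix(stats::rnorm(625, 0, 1.2), 25, 25), 0),
                  origin = ref$origin, spacing = ref$spacing)
  rates <- vapply(list(gamma_criteria(3, 2), gamma_criteria(2, 2),
                       gamma_criteria(2, 1), gamma_criteria(1, 1)),
                  function(cr) pass_rate(gamma_map(ref, ev, cr)), 0.0)
  expect_true(all(diff(rates) <= 0))  # 3%/2mm >= 2%/2mm >= 2%/1mm >= 1%/1mm
})

test_that("local normalisation is pointwise at least as strict as global", {
  set.seed(45)
  ref <- smooth_random_grid(20, 2.5)
  ev <- dose_grid(pmax(ref$values + matrix(stats::rnorm(400, 0, 1), 20, 20), 0),
                  origin = ref$origin, spacing = ref$spacing)
  gg <- gamma_map(ref, ev, gamma_criteria(3, 2, "global"))
  gl <- gamma_map(ref, ev, gamma_criteria(3, 2, "local"))
  m <- gg$points$in_mask
  expect_true(all(gl$points$gamma[m] >= gg$points$gamma[m] - 1e-12))
})

test_that("gamma is invariant under joint rescaling with global normalisation", {
  set.seed(46)
  ref <- smooth_random_grid(18, 2.5)
  ev <- dose_grid(pmax(ref$values + matrix(stats::rnorm(324, 0, 1.5), 18, 18), 0),
                  origin = ref$origin, spacing = ref$spacing)
  cr <- gamma_criteria(3, 2, "global")
  g1 <- gamma_map(ref, ev, cr)$points$gamma
  ref2 <- dose_grid(ref$values * 7, origin = ref$origin, spacing = ref$spacing)
  ev2 <- dose_grid(ev$values * 7, origin = ev$origin, spacing = ev$spacing)
  g2 <- gamma_map(ref2, ev2, cr)$points$gamma
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("refining the evaluated sub-grid never increases any gamma", {
  set.seed(47)
  ref <- smooth_random_grid(15, 2.5)
  ev <- dose_grid(pmax(ref$values + matrix(stats::rnorm(225, 0, 2), 15, 15), 0),
                  origin = ref$origin, spacing = ref$spacing)
  cr <- gamma_criteria(3, 2, "global")
  coarse <- gamma_map(ref, ev, cr, step = 0.4)$points$gamma
  fine <- gamma_map(ref, ev, cr, step = 0.2)$points$gamma
  expect_true(all(fine <= coarse + 1e-12, na.rm = TRUE))
})

test_that("all-below-threshold references give an empty result with warning", {
  set.seed(49)
  lo <- smooth_random_grid(10, 2.5)
  # normalisation dose prescribed from a larger calculated volume: every
  # point of this low-dose subset falls below 10% of it
  expect_warning(
    res <- gamma_map(lo, lo, gamma_criteria(3, 2, threshold = 10),
                     norm_dose = 20 * max(lo$values)),
    "below the low-dose threshold"
  )
  expect_true(all(!res$points$in_mask))
  expect_error(pass_rate(res), "no evaluable")
})

test_that("profile comparison: identity is zero, a 1 mm shift stresses the penumbra", {
  f <- rectangular_field(c(100, 100), penumbra_sigma = 3)
  calc <- generate_vmat_dosemap(f)
  p0 <- profile_compare(calc, calc, line = list(direction = "lateral", offset = 0))
  expect_true(all(p0$gamma[p0$calculated > 0.1] < 1e-9))
  # measured shifted +1 mm relative to calculated
  shifted <- dose_grid(calc$values, origin = calc$origin + c(1, 0),
                       spacing = calc$spacing)
  p1 <- profile_compare(shifted, calc, line = list(direction = "lateral", offset = 0),
                        criteria = gamma_criteria(3, 2, cap = 2))
  plateau <- abs(p1$pos) < 35  # interior, away from the +-50 mm field edges
  penumbra <- p1$calculated > 0.2 * max(p1$calculated) &
    p1$calculated < 0.8 * max(p1$calculated)
  expect_lt(max(p1$gamma[plateau]), 0.1)
  expect_gt(max(p1$gamma[penumbra]), max(p1$gamma[plateau]))
  # the diagonal line works and stays finite
  pd <- profile_compare(calc, calc, line = list(direction = "diagonal", offset = 0))
  expect_true(all(is.finite(pd$gamma)))
})

test_that("3D gamma kernel: identity passes and a uniform offset matches closed form", {
  set.seed(48)
  block <- array(stats::runif(10 * 10 * 6, 50, 100), dim = c(10, 10, 6))
  cr <- gamma_criteria(3, 2, "global")
  res <- gamma_volume(block, block, origin = c(0, 0, 0), spacing = c(2, 2, 2),
                      criteria = cr)
  expect_true(all(res$points$gamma[res$points$in_mask] == 0))
  # uniform block offset by exactly 3% of max: gamma = 1 everywhere
  uni <- array(100, dim = c(8, 8, 4))
  res2 <- gamma_volume(uni, uni * 1.03, origin = c(0, 0, 0), spacing = c(2, 2, 2),
                       criteria = cr)
  expect_equal(max(res2$points$gamma[res2$points$in_mask]), 1, tolerance = 1e-9)
})
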