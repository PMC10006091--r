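# Shared fixtures and independent oracles.

# smooth random planar dose on a regular grid (moving-average-filtered noise,
# rescaled to [0, 100]); smooth enough that linear interpolation error is
# small relative to the gamma tolerances under test
smooth_random_grid <- function(n = 20, spacing = 2.5, smooth = 3) {
  z <- matrix(stats::rnorm((n + 2 * smooth)^2), n + 2 * smooth)
  k <- seq_len(2 * smooth + 1)
  sm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sm[i, j] <- mean(z[i + k - 1, j + k - 1])
    }
  }
  sm <- (sm - min(sm)) / (max(sm) - min(sm)) * 100
  half <- (n - 1) * spacing / 2
  dose_grid(sm, origin = c(-half, -half), spacing = c(spacing, spacing))
}

# independent brute-force gamma oracle: exhaustive search over a very fine
# evaluated grid built with stats::approx-based separable interpolation
# (no shared code with the implementation kernel), no search cap
gamma_oracle <- function(reference, evaluated, criteria, fine = criteria$dta / 20,
                         reach = 3 * criteria$dta) {
  rx <- grid_x(reference); ry <- grid_y(reference)
  ex <- grid_x(evaluated); ey <- grid_y(evaluated)
  fx <- seq(min(ex), max(ex), by = fine)
  fy <- seq(min(ey), max(ey), by = fine)
  # separable bilinear: rows then columns
  tmp <- apply(evaluated$values, 2, function(col) stats::approx(ex, col, xout = fx)$y)
  fv <- t(apply(tmp, 1, function(row) stats::approx(ey, row, xout = fy)$y))
  max_ref <- max(reference$values)
  th <- criteria$threshold / 100 * max_ref
  out <- matrix(NA_real_, length(rx), length(ry))
  for (i in seq_along(rx)) {
    for (j in seq_along(ry)) {
      dref <- reference$values[i, j]
      if (dref < th) next
      dd_abs <- if (criteria$norm == "global") criteria$dd / 100 * max_ref
        else criteria$dd / 100 * dref
      xi <- which(abs(fx - rx[i]) <= reach)
      yj <- which(abs(fy - ry[j]) <= reach)
      dist2 <- outer((fx[xi] - rx[i])^2, (fy[yj] - ry[j])^2, "+")
      keep <- dist2 <= criteria$cap^2
      gg <- sqrt(dist2 / criteria$dta^2 + ((fv[xi, yj] - dref) / dd_abs)^2)
      out[i, j] <- min(gg[keep])
    }
  }
  out
}

# pair-counting AUC oracle: P(test more error-like than control) + half ties
auc_oracle <- function(control, test) {
  s <- 0
  for (tv in test) {
    for (cv in control) {
      s <- s + (tv < cv) + 0.5 * (tv == cv)
    }
  }
  s / (length(test) * length(control))
}

# single open leaf pair as a field_spec (all other pairs closed)
single_pair_field <- function(pair, x_open = c(-50, 50), weight = 1,
                              penumbra_sigma = 0, collimator_deg = 0) {
  ap <- matrix(NA_real_, 60, 2)
  ap[pair, ] <- x_open
  field_spec(list(list(apertures = ap, weight = weight)),
             penumbra_sigma = penumbra_sigma, collimator_deg = collimator_deg)
}
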