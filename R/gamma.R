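# Gamma-index comparison of reference (calculated) vs evaluated (measured /
# reconstructed) dose distributions.

#' Gamma acceptance criteria
#'
#' @param dd dose tolerance, % of the normalisation dose (> 0).
#' @param dta distance-to-agreement, mm (> 0).
#' @param norm `"global"` (tolerance referenced to the maximum reference
#'   dose) or `"local"` (to the local reference dose).
#' @param threshold low-dose threshold, % of the maximum reference dose;
#'   reference points below it are excluded (default 10).
#' @param cap search-radius cap, mm; defaults to `3 * dta` (profile
#'   comparisons conventionally use a 2 mm cap).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dd = 3, dta = 2, norm = c("global", "local"),
                           threshold = 10, cap = 3 * dta) {
  norm <- match.arg(norm)
  if (dd <= 0 || dta <= 0) stop("gamma_criteria: dd and dta must be > 0", call. = FALSE)
  if (threshold < 0 || threshold >= 100) {
    stop("gamma_criteria: threshold must be in [0, 100)", call. = FALSE)
  }
  structure(list(dd = dd, dta = dta, norm = norm, threshold = threshold,
                 cap = cap),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %s normalisation, TH %g%%, cap %g mm\n",
              x$dd, x$dta, x$norm, x$threshold, x$cap))
  invisible(x)
}

format_criteria <- function(cr) {
  sprintf("%g%%/%gmm %s", cr$dd, cr$dta, cr$norm)
}

ref_points <- function(reference) {
  if (inherits(reference, "dose_grid")) {
    xs <- grid_x(reference); ys <- grid_y(reference)
    data.frame(x = rep(xs, times = length(ys)),
               y = rep(ys, each = length(xs)),
               dose = as.vector(reference$values))
  } else if (inherits(reference, "measured_map")) {
    data.frame(x = reference$x, y = reference$y, dose = reference$dose)
  } else {
    df <- as.data.frame(reference)
    stopifnot(all(c("x", "y", "dose") %in% names(df)))
    df[c("x", "y", "dose")]
  }
}

# fine evaluated grid (list: values matrix possibly holding NA, origin, step)
eval_fine <- function(evaluated, step, pad = 0) {
  if (inherits(evaluated, "dose_grid")) {
    ext <- grid_extent(evaluated)
    xs <- seq(ext$x[1], ext$x[2], by = step)
    ys <- seq(ext$y[1], ext$y[2], by = step)
    v <- lattice_fine_cpp(evaluated$values,
                          evaluated$origin[1], evaluated$spacing[1],
                          evaluated$origin[2], evaluated$spacing[2],
                          FALSE, xs[1], ys[1], step, length(xs), length(ys))
  } else if (inherits(evaluated, "measured_map")) {
    xs <- seq(min(evaluated$x) - pad, max(evaluated$x) + pad, by = step)
    ys <- seq(min(evaluated$y) - pad, max(evaluated$y) + pad, by = step)
    lat <- as_lattice(evaluated)
    v <- lattice_fine_cpp(lat$values,
                          lat$ux[1], lat$ux[2] - lat$ux[1],
                          lat$uy[1], lat$uy[2] - lat$uy[1],
                          lat$rotated, xs[1], ys[1], step,
                          length(xs), length(ys))
  } else {
    stop("gamma_map: evaluated must be a dose_grid or measured_map", call. = FALSE)
  }
  list(values = v, origin = c(xs[1], ys[1]), step = step)
}

#' Gamma-index map
#'
#' For every reference point above the low-dose threshold, the gamma index
#' is the minimum over evaluated positions r of
#' `sqrt(|r - r_ref|^2 / DTA^2 + (D_eval(r) - D_ref)^2 / dD_abs^2)`, with the
#' evaluated distribution linearly interpolated onto a fine sub-grid
#' (default step `DTA / 10`) and the search restricted to the criteria's
#' radius cap. `dD_abs` is `dd% * max(D_ref)` for global normalisation and
#' `dd% * D_ref` locally. A point passes if gamma <= 1.
#'
#' @param reference the calculated distribution: a [dose_grid()], a
#'   `measured_map`, or a data.frame with `x`, `y`, `dose`.
#' @param evaluated the measured/reconstructed distribution: a
#'   [dose_grid()] or `measured_map`.
#' @param criteria a [gamma_criteria()].
#' @param step evaluated sub-grid step, mm (default `dta / 10`).
#' @param norm_dose normalisation dose for the global dose tolerance and the
#'   low-dose threshold; defaults to the maximum of the supplied reference
#'   (use the maximum of the full calculated volume when passing a subset).
#' @return An object of class `gamma_result`: data.frame `points`
#'   (`x`, `y`, `ref_dose`, `gamma`, `pass`, `in_mask`), the criteria, the
#'   normalisation dose, and `n_undefined` (masked points with no evaluated
#'   data inside the search cap).
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      step = criteria$dta / 10, norm_dose = NULL) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  pts <- ref_points(reference)
  max_ref <- if (is.null(norm_dose)) max(pts$dose) else norm_dose
  if (max_ref <= 0) stop("gamma_map: reference has no positive dose", call. = FALSE)
  mask <- pts$dose >= criteria$threshold / 100 * max_ref
  if (!any(mask)) {
    warning("gamma_map: all reference points below the low-dose threshold")
    res <- structure(
      list(points = cbind(pts, gamma = NA_real_, pass = NA, in_mask = FALSE),
           criteria = criteria, norm_dose = max_ref, n_undefined = 0L),
      class = "gamma_result"
    )
    return(res)
  }
  sub <- pts[mask, , drop = FALSE]
  dd_abs <- if (criteria$norm == "global") {
    rep(criteria$dd / 100 * max_ref, nrow(sub))
  } else {
    pmax(criteria$dd / 100 * sub$dose, 1e-12)
  }
  ev <- eval_fine(evaluated, step, pad = criteria$cap)
  g <- gamma_search_cpp(sub$x, sub$y, sub$dose, dd_abs,
                        ev$values, ev$origin, ev$step,
                        criteria$dta, criteria$cap)
  # the reference position itself is always a candidate (zero distance)
  e0 <- if (inherits(evaluated, "dose_grid")) {
    interp_grid(evaluated, sub$x, sub$y)
  } else {
    interp_map(evaluated, sub$x, sub$y)
  }
  g0 <- abs(e0 - sub$dose) / dd_abs
  g <- pmin(g, g0, na.rm = TRUE)
  gamma <- rep(NA_real_, nrow(pts))
  gamma[mask] <- g
  n_undef <- sum(is.na(g))
  if (n_undef > 0) {
    warning(sprintf("gamma_map: %d masked reference point(s) have no evaluated data within the search cap", n_undef))
  }
  pts$gamma <- gamma
  pts$pass <- !is.na(gamma) & gamma <= 1
  pts$in_mask <- mask
  names(pts)[names(pts) == "dose"] <- "ref_dose"
  structure(
    list(points = pts, criteria = criteria, norm_dose = max_ref,
         n_undefined = n_undef),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: %d reference points, %d in mask, pass rate %.2f%%\n",
              format_criteria(x$criteria), nrow(x$points),
              sum(x$points$in_mask), pass_rate(x)))
  invisible(x)
}

#' Percent of reference points passing (gamma <= 1)
#'
#' `100 * #(gamma <= 1 and above threshold) / #(above threshold)`. Masked
#' points whose gamma is undefined (no evaluated data within the cap) are
#' excluded from both counts; their number is reported in the result.
#'
#' @param result a [gamma_map()] result.
#' @return percent pass in \[0, 100\].
#' @export
pass_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$points$gamma[result$points$in_mask]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("pass_rate: no evaluable reference points", call. = FALSE)
  100 * sum(g <= 1) / length(g)
}

#' Export a gamma result as CSV
#'
#' Columns: `x_mm`, `y_mm`, `ref_dose`, `gamma`, `pass`.
#' @param result a `gamma_result`.
#' @param path file path.
#' @export
write_gamma_result <- function(result, path) {
  df <- result$points[result$points$in_mask, ]
  utils::write.csv(
    data.frame(x_mm = df$x, y_mm = df$y, ref_dose = df$ref_dose,
               gamma = df$gamma, pass = df$pass),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Profile comparison with per-point gamma
#'
#' Samples the measured and calculated distributions along a line in the
#' detector plane and computes, for each calculated (reference) point, the
#' minimum gamma over the measured profile within a search distance
#' (default cap 2 mm, the convention for profile views), with the measured
#' profile linearly interpolated at `dta / 10`.
#'
#' @param measured a `measured_map` or [dose_grid()].
#' @param calculated a [dose_grid()].
#' @param line list with `direction` (`"lateral"`, `"longitudinal"` or
#'   `"diagonal"` — the positive-slope diagonal) and `offset` (mm,
#'   perpendicular offset from the axis).
#' @param criteria a [gamma_criteria()]; the cap defaults to 2 mm here.
#' @param step sampling step along the line, mm.
#' @return data.frame with `pos` (mm along the line), `measured`,
#'   `calculated` and `gamma`.
#' @export
profile_compare <- function(measured, calculated, line = list(direction = "lateral", offset = 0),
                            criteria = gamma_criteria(cap = 2), step = 1) {
  stopifnot(inherits(calculated, "dose_grid"))
  dirs <- list(
    lateral = list(d = c(1, 0), n = c(0, 1)),
    longitudinal = list(d = c(0, 1), n = c(1, 0)),
    diagonal = list(d = c(1, 1) / sqrt(2), n = c(-1, 1) / sqrt(2))
  )
  if (!line$direction %in% names(dirs)) {
    stop("profile_compare: direction must be lateral, longitudinal or diagonal", call. = FALSE)
  }
  dv <- dirs[[line$direction]]$d
  nv <- dirs[[line$direction]]$n
  off <- if (is.null(line$offset)) 0 else line$offset
  ext <- grid_extent(calculated)
  tmax <- min(abs(c(ext$x, ext$y))) * if (line$direction == "diagonal") sqrt(2) else 1
  t_ref <- seq(-tmax, tmax, by = step)
  px <- off * nv[1] + t_ref * dv[1]
  py <- off * nv[2] + t_ref * dv[2]
  d_calc <- interp_grid(calculated, px, py)
  sample_meas <- function(x, y) {
    if (inherits(measured, "dose_grid")) interp_grid(measured, x, y) else interp_map(measured, x, y)
  }
  d_meas <- sample_meas(px, py)
  keep <- !is.na(d_calc) & !is.na(d_meas)
  t_ref <- t_ref[keep]; px <- px[keep]; py <- py[keep]
  d_calc <- d_calc[keep]; d_meas <- d_meas[keep]
  if (length(t_ref) == 0) stop("profile_compare: line outside both distributions", call. = FALSE)
  max_ref <- max(calculated$values)
  dd_abs <- if (criteria$norm == "global") {
    rep(criteria$dd / 100 * max_ref, length(t_ref))
  } else {
    pmax(criteria$dd / 100 * d_calc, 1e-12)
  }
  # 1D search along the line at dta/10
  fine_t <- seq(min(t_ref) - criteria$cap, max(t_ref) + criteria$cap,
                by = criteria$dta / 10)
  fine_m <- sample_meas(off * nv[1] + fine_t * dv[1], off * nv[2] + fine_t * dv[2])
  gam <- vapply(seq_along(t_ref), function(i) {
    sel <- which(abs(fine_t - t_ref[i]) <= criteria$cap & !is.na(fine_m))
    if (length(sel) == 0) return(NA_real_)
    min(sqrt((fine_t[sel] - t_ref[i])^2 / criteria$dta^2 +
               (fine_m[sel] - d_calc[i])^2 / dd_abs[i]^2))
  }, 0.0)
  data.frame(pos = t_ref, measured = d_meas, calculated = d_calc, gamma = gam)
}

#' 3D gamma on voxel dose blocks
#'
#' Same kernel as [gamma_map()] applied to voxel grids: the evaluated block
#' is trilinearly resampled to a fine sub-grid (default `dta / 5` for
#' desk-scale volumes) and each masked reference voxel takes the minimum
#' combined discrepancy within the cap.
#'
#' @param reference,evaluated 3D dose arrays on the same coordinate frame.
#' @param origin,spacing length-3 voxel origin and spacing, mm.
#' @param criteria a [gamma_criteria()].
#' @param step fine sub-grid step, mm.
#' @return a `gamma_result` whose points carry `x`, `y`, `z`.
#' @export
gamma_volume <- function(reference, evaluated, origin, spacing,
                         criteria = gamma_criteria(), step = criteria$dta / 5) {
  stopifnot(is.array(reference), is.array(evaluated), length(dim(reference)) == 3)
  max_ref <- max(reference)
  dims <- dim(reference)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- expand.grid(x = xs, y = ys, z = zs)
  pts$dose <- as.vector(reference)
  mask <- pts$dose >= criteria$threshold / 100 * max_ref
  if (!any(mask)) stop("gamma_volume: all voxels below threshold", call. = FALSE)
  sub <- pts[mask, , drop = FALSE]
  dd_abs <- if (criteria$norm == "global") {
    rep(criteria$dd / 100 * max_ref, nrow(sub))
  } else {
    pmax(criteria$dd / 100 * sub$dose, 1e-12)
  }
  fine <- trilinear_resample(evaluated, origin, spacing, step)
  g <- gamma_search3d_cpp(sub$x, sub$y, sub$z, sub$dose, dd_abs,
                          fine$values, dim(fine$values), fine$origin,
                          rep(fine$step, 3), criteria$dta, criteria$cap)
  if (identical(dim(evaluated), dims)) {
    # the reference voxel itself is always a candidate (zero distance)
    g0 <- abs(as.vector(evaluated)[mask] - sub$dose) / dd_abs
    g <- pmin(g, g0, na.rm = TRUE)
  }
  gamma <- rep(NA_real_, nrow(pts))
  gamma[mask] <- g
  pts$gamma <- gamma
  pts$pass <- !is.na(gamma) & gamma <= 1
  pts$in_mask <- mask
  names(pts)[names(pts) == "dose"] <- "ref_dose"
  structure(
    list(points = pts, criteria = criteria, norm_dose = max_ref,
         n_undefined = sum(is.na(g))),
    class = "gamma_result"
  )
}

trilinear_resample <- function(arr, origin, spacing, step) {
  dims <- dim(arr)
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  new_axes <- lapply(1:3, function(a) seq(axes[[a]][1], axes[[a]][dims[a]], by = step))
  # separable linear interpolation, one axis at a time
  out <- arr
  for (a in 1:3) {
    d <- dim(out)
    m <- matrix(aperm(out, c(a, setdiff(1:3, a))), nrow = d[a])
    mi <- apply(m, 2, function(col) stats::approx(axes[[a]], col, xout = new_axes[[a]])$y)
    newd <- d; newd[a] <- length(new_axes[[a]])
    out <- aperm(array(mi, dim = c(newd[a], newd[setdiff(1:3, a)])),
                 order(c(a, setdiff(1:3, a))))
  }
  list(values = out, origin = vapply(new_axes, `[`, 0.0, 1), step = step)
}
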