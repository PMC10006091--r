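# 3D dose reconstruction on a voxel phantom from a planar measured map:
# TPR ratio x inverse square along divergent rays, with water-equivalent
# depths from length-weighted electron densities.

phantom_density_at <- function(phantom, x, y, z) {
  ix <- round((x - phantom$x[1]) / phantom$spacing) + 1
  iy <- round((y - phantom$y[1]) / phantom$spacing) + 1
  iz <- round((z - phantom$z[1]) / phantom$spacing) + 1
  nx <- length(phantom$x); ny <- length(phantom$y); nz <- length(phantom$z)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
  dens <- rep(0, length(x))
  inside <- rep(FALSE, length(x))
  if (any(ok)) {
    idx <- cbind(ix[ok], iy[ok], iz[ok])
    dens[ok] <- phantom$density[idx]
    inside[ok] <- phantom$contour[idx]
  }
  list(density = dens, inside = inside)
}

#' Ray path from the focus through a point
#'
#' Traces the divergent ray from the X-ray focus through `target`
#' (phantom-frame coordinates, mm), sampling the phantom at a fixed
#' sub-voxel step (`spacing / 4`). Records, from the contour entry point to
#' the target, the traversed sample densities, plus the focus-target
#' distance.
#'
#' @param phantom a [make_phantom()] object.
#' @param target length-3 point c(x, y, z), mm.
#' @param step sampling step, mm (default `spacing / 4`).
#' @return An object of class `ray_path`: `target`, `a` (focus distance,
#'   mm), `geom_depth` (entry-to-target geometric depth, mm), `densities`,
#'   `step_len`.
#' @export
ray_path <- function(phantom, target, step = phantom$spacing / 4) {
  stopifnot(inherits(phantom, "voxel_phantom"), length(target) == 3)
  focus <- phantom$focus
  dirv <- target - focus
  a <- sqrt(sum(dirv^2))
  dirv <- dirv / a
  z0 <- phantom$z[1] - phantom$spacing / 2
  t0 <- (z0 - focus[3]) / dirv[3]
  ts <- seq(t0, a, by = step)
  px <- focus[1] + ts * dirv[1]
  py <- focus[2] + ts * dirv[2]
  pz <- focus[3] + ts * dirv[3]
  q <- phantom_density_at(phantom, px, py, pz)
  first_in <- which(q$inside)[1]
  if (is.na(first_in)) stop("ray_path: ray misses the phantom contour", call. = FALSE)
  sel <- seq(first_in, length(ts))
  structure(
    list(target = target, a = a,
         geom_depth = a - ts[first_in],
         densities = q$density[sel],
         step_len = step),
    class = "ray_path"
  )
}

#' Water-equivalent depth along a ray
#'
#' `Z = Z_geom * sum(rho_i) / (n * rho_water)`: the geometric depth from the
#' contour entry point scaled by the mean relative electron density of the
#' traversed samples (rho_water = 1).
#'
#' @param ray a [ray_path()], or a length-3 target point (in which case
#'   `phantom` must be supplied).
#' @param phantom a [make_phantom()] object (needed when `ray` is a point).
#' @return water-equivalent depth, mm.
#' @export
water_equivalent_depth <- function(ray, phantom = NULL) {
  if (!inherits(ray, "ray_path")) {
    if (is.null(phantom)) stop("water_equivalent_depth: supply a phantom", call. = FALSE)
    ray <- ray_path(phantom, ray)
  }
  ray$geom_depth * mean(ray$densities) / 1
}

#' Reconstruct dose at one voxel from one detector reading
#'
#' `D_CT = D_Det * TPR(Z_CT) / TPR(Z_Det) * (a_Det / a_CT)^2`: the TPR ratio
#' accounts for the different water-equivalent thickness of overlying
#' material, the squared distance ratio for beam divergence.
#'
#' @param d_det measured dose at the detector.
#' @param z_det,z_ct water-equivalent depths of detector and voxel, mm.
#' @param a_det,a_ct focus distances of detector and voxel, mm.
#' @param beam a [make_beam_model()].
#' @return reconstructed dose `D_CT`.
#' @export
reconstruct_point <- function(d_det, z_det, z_ct, a_det, a_ct, beam) {
  stopifnot(inherits(beam, "beam_model"))
  if (any(c(z_det, z_ct) < 0) || any(c(a_det, a_ct) <= 0)) {
    stop("reconstruct_point: depths must be >= 0 and distances > 0", call. = FALSE)
  }
  t_det <- beam$tpr(z_det)
  if (any(t_det == 0)) stop("reconstruct_point: TPR(Z_Det) = 0", call. = FALSE)
  d_det * beam$tpr(z_ct) / t_det * (a_det / a_ct)^2
}

#' Reconstruct a 3D dose volume from a planar measured map
#'
#' For every sample point of the map a divergent ray from the focus is
#' marched through the phantom at a fixed sub-voxel step, accumulating the
#' water-equivalent depth; dose is assigned along the ray at every voxel
#' layer with [reconstruct_point()], then linearly interpolated between
#' rays in the detector-plane parameterisation (each voxel is
#' back-projected through the focus onto the detector plane). Voxels
#' outside the contour are zero; in-contour voxels outside the
#' interpolation hull are zeroed and counted in the coverage report.
#'
#' @param map a `measured_map` (standard or coalesced acquisition).
#' @param phantom a [make_phantom()] object; its `det_depth` is the depth
#'   of the measurement plane (the detector reads at its own depth inside
#'   the phantom).
#' @param beam a [make_beam_model()].
#' @param step ray-marching step, mm (default `spacing / 4`).
#' @return An object of class `reconstructed_dose`: 3D `values` array on
#'   the phantom grid, voxel coordinates, and `coverage` (fraction of
#'   in-contour voxels inside the interpolation hull).
#' @export
reconstruct_volume <- function(map, phantom, beam, step = phantom$spacing / 4) {
  stopifnot(inherits(map, "measured_map"), inherits(phantom, "voxel_phantom"),
            inherits(beam, "beam_model"))
  nray <- length(map$x)
  if (nray == 0) stop("reconstruct_volume: empty measured map", call. = FALSE)
  fz <- phantom$focus[3]
  z_det <- phantom$det_depth
  nz <- length(phantom$z)

  # march all rays simultaneously, parameterised by depth z
  z_start <- phantom$z[1] - phantom$spacing / 2
  zs_march <- seq(z_start, max(phantom$z) + step / 2, by = step)
  # per-ray path length per unit depth (divergence correction)
  dirn <- sqrt((map$x / (z_det - fz))^2 + (map$y / (z_det - fz))^2 + 1)
  # march index at which each voxel layer (and the detector plane) is crossed
  k_layer <- round((phantom$z - z_start) / step) + 1L
  k_det <- round((z_det - z_start) / step) + 1L

  sum_rho <- rep(0, nray)
  n_samp <- rep(0L, nray)
  entry_z <- rep(NA_real_, nray)
  wed_layers <- matrix(NA_real_, nray, nz)
  wed_det <- rep(NA_real_, nray)
  record <- function(zk) {
    geom <- (zk - entry_z) * dirn
    ifelse(is.na(entry_z) | n_samp == 0, NA_real_,
           pmax(geom, 0) * sum_rho / pmax(n_samp, 1L))
  }
  lookup <- match(seq_along(zs_march), k_layer)
  for (k in seq_along(zs_march)) {
    zk <- zs_march[k]
    mk <- (zk - fz) / (z_det - fz)
    q <- phantom_density_at(phantom, map$x * mk, map$y * mk, rep(zk, nray))
    newly <- q$inside & is.na(entry_z)
    entry_z[newly] <- zk
    inb <- !is.na(entry_z)
    sum_rho[inb] <- sum_rho[inb] + q$density[inb]
    n_samp[inb] <- n_samp[inb] + 1L
    if (!is.na(lookup[k])) wed_layers[, lookup[k]] <- record(zk)
    if (k == k_det) wed_det <- record(zk)
  }
  missed <- is.na(wed_det)
  if (all(missed)) stop("reconstruct_volume: no ray intersects the phantom contour", call. = FALSE)

  a_det <- sqrt(map$x^2 + map$y^2 + (z_det - fz)^2)
  tpr_det <- beam$tpr(ifelse(missed, 0, wed_det))
  if (any(tpr_det[!missed] == 0)) stop("reconstruct_volume: TPR(Z_Det) = 0", call. = FALSE)

  nx <- length(phantom$x); ny <- length(phantom$y)
  vx <- rep(phantom$x, times = ny)
  vy <- rep(phantom$y, each = nx)
  values <- array(0, dim = c(nx, ny, nz))
  n_uncovered <- 0L
  for (l in seq_len(nz)) {
    ml <- (phantom$z[l] - fz) / (z_det - fz)
    d_ray <- rep(NA_real_, nray)
    ok <- !missed & !is.na(wed_layers[, l])
    if (any(ok)) {
      d_ray[ok] <- reconstruct_point(
        map$dose[ok], wed_det[ok], wed_layers[ok, l],
        a_det[ok], ml * a_det[ok], beam
      )
    }
    ray_map <- measured_map(map$x, map$y, d_ray, model = map$model)
    layer <- interp_map(ray_map, vx / ml, vy / ml)
    in_contour <- phantom$contour[, , l]
    vals <- matrix(layer, nx, ny)
    uncovered <- in_contour & is.na(vals)
    n_uncovered <- n_uncovered + sum(uncovered)
    vals[is.na(vals) | !in_contour] <- 0
    values[, , l] <- pmax(vals, 0)
  }
  n_in <- sum(phantom$contour)
  structure(
    list(values = values, x = phantom$x, y = phantom$y, z = phantom$z,
         spacing = phantom$spacing, phantom_kind = phantom$kind,
         source = map$model,
         coverage = list(n_in_contour = n_in, n_uncovered = n_uncovered,
                         fraction_covered = 1 - n_uncovered / n_in)),
    class = "reconstructed_dose"
  )
}

#' @export
print.reconstructed_dose <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_dose> %d x %d x %d voxels @ %g mm, max %.4g, coverage %.1f%%\n",
    length(x$x), length(x$y), length(x$z), x$spacing, max(x$values),
    100 * x$coverage$fraction_covered
  ))
  invisible(x)
}

#' Write a reconstructed volume as stacked plain-text grids
#'
#' One dose-grid file per voxel layer (`<prefix>_z<depth>mm.txt`) plus a
#' `<prefix>_meta.txt` with the layer depths.
#'
#' @param dose a `reconstructed_dose`.
#' @param prefix path prefix.
#' @export
write_reconstructed_dose <- function(dose, prefix) {
  paths <- character(length(dose$z))
  for (l in seq_along(dose$z)) {
    g <- dose_grid(dose$values[, , l], origin = c(dose$x[1], dose$y[1]),
                   spacing = rep(dose$spacing, 2))
    paths[l] <- sprintf("%s_z%gmm.txt", prefix, dose$z[l])
    write_dose_grid(g, paths[l])
  }
  writeLines(c("layer_depths_mm", paste(fmt17(dose$z), collapse = " ")),
             paste0(prefix, "_meta.txt"))
  invisible(paths)
}

# ---- DVH -------------------------------------------------------------------

#' Cumulative dose-volume histogram and D50
#'
#' Cumulative DVH of the masked voxels on a dose-bin grid of 0.1% of the
#' maximum dose per bin; `D50` (dose to 50% of the volume) by linear
#' inverse interpolation of the cumulative curve.
#'
#' @param dose a `reconstructed_dose`, or a numeric array of dose values.
#' @param mask logical array (same dimensions) selecting the structure;
#'   must be non-empty.
#' @param reference optional reference D50 against which the absolute
#'   percent difference `|(D - D_ref)/D_ref| * 100` is reported.
#' @return An object of class `dvh_result`: `curve` (data.frame `dose`,
#'   `volume_fraction`), `d50`, and `d50_percent_diff` when a reference is
#'   given.
#' @export
compute_dvh <- function(dose, mask = NULL, reference = NULL) {
  vals <- if (inherits(dose, "reconstructed_dose")) dose$values else dose
  if (is.null(mask)) mask <- array(TRUE, dim = dim(vals))
  if (!any(mask)) stop("compute_dvh: empty structure mask", call. = FALSE)
  v <- vals[mask]
  dmax <- max(v)
  bins <- seq(0, dmax, length.out = 1001)  # 0.1% of max per bin
  frac <- vapply(bins, function(b) mean(v >= b), 0.0)
  d50 <- if (dmax == 0) 0 else {
    # first crossing of 0.5 on the monotone non-increasing curve
    i <- which(frac < 0.5)[1]
    if (is.na(i)) dmax
    else if (i == 1) 0
    else bins[i - 1] + (0.5 - frac[i - 1]) * (bins[i] - bins[i - 1]) /
      (frac[i] - frac[i - 1])
  }
  out <- list(curve = data.frame(dose = bins, volume_fraction = frac), d50 = d50)
  if (!is.null(reference)) {
    out$d50_percent_diff <- abs((d50 - reference) / reference) * 100
  }
  structure(out, class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("<dvh_result> D50 = %.4g%s\n", x$d50,
              if (!is.null(x$d50_percent_diff))
                sprintf(", |%%diff| vs reference = %.3g%%", x$d50_percent_diff)
              else ""))
  invisible(x)
}
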