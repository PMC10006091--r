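# Ground-truth planar dose synthesis, error injection, phantoms and beam model.

edge_profile <- function(u, lo, hi, sigma) {
  # top-hat [lo, hi) convolved with Gaussian(sigma); sigma = 0 -> indicator.
  # Half-open so that abutting leaf strips telescope without double counting.
  if (sigma > 0) {
    stats::pnorm((u - lo) / sigma) - stats::pnorm((u - hi) / sigma)
  } else {
    as.double(u >= lo & u < hi)
  }
}

#' Generate a VMAT-like planar dose map
#'
#' Renders a `field_spec` onto a regular grid: each open leaf pair of each
#' segment contributes `weight` times the product of an erf-edged profile
#' between the leaf tips (along leaf travel) and an erf-edged top-hat over
#' the leaf width, i.e. the aperture rectangle convolved with an isotropic
#' Gaussian penumbra kernel of the spec's `penumbra_sigma`; the whole
#' aperture is rotated by the collimator angle. Unit fluence: a one-segment
#' field of weight `w` has plateau dose `w`.
#'
#' @param spec a [field_spec()].
#' @param seed optional integer; only used when `noise_sd > 0` (the dose
#'   model itself is deterministic).
#' @param extent half-width of the (square) grid, mm; the grid spans
#'   `[-extent, extent]` on both axes and must cover the 270 x 270 mm
#'   detector area when used for array sampling.
#' @param spacing grid spacing, mm (must be <= 1 mm).
#' @param noise_sd additive Gaussian noise sd in dose units (default 0).
#' @return a [dose_grid()].
#' @export
generate_vmat_dosemap <- function(spec, seed = NULL, extent = 160, spacing = 1,
                                  noise_sd = 0) {
  stopifnot(inherits(spec, "field_spec"))
  if (spacing > 1) stop("generate_vmat_dosemap: grid spacing must be <= 1 mm", call. = FALSE)
  xs <- seq(-extent, extent, by = spacing)
  ys <- xs
  nx <- length(xs); ny <- length(ys)
  # aperture must lie inside the grid
  mlc <- spec$mlc
  for (s in spec$segments) {
    ap <- s$apertures
    open <- !is.na(ap[, 1])
    if (any(open) &&
        (min(ap[open, 1]) < -extent || max(ap[open, 2]) > extent ||
         min(mlc$lower[open]) < -extent || max(mlc$upper[open]) > extent)) {
      stop("generate_vmat_dosemap: aperture extends outside the dose grid", call. = FALSE)
    }
  }
  theta <- spec$collimator_deg * pi / 180
  X <- matrix(rep(xs, times = ny), nx, ny)
  Y <- matrix(rep(ys, each = nx), nx, ny)
  # rotate plane coordinates into the collimator frame
  U <- cos(theta) * X + sin(theta) * Y   # along leaf travel
  V <- -sin(theta) * X + cos(theta) * Y  # across leaves
  dose <- matrix(0, nx, ny)
  sg <- spec$penumbra_sigma
  band <- 6 * sg  # beyond ~6 sigma the erf edge contributes nothing
  for (s in spec$segments) {
    ap <- s$apertures
    open <- which(!is.na(ap[, 1]) & !is.na(ap[, 2]))
    for (p in open) {
      # each strip only acts within a band across the leaf axis
      idx <- which(V >= mlc$lower[p] - band & V < mlc$upper[p] + band)
      dose[idx] <- dose[idx] + s$weight *
        edge_profile(U[idx], ap[p, 1], ap[p, 2], sg) *
        edge_profile(V[idx], mlc$lower[p], mlc$upper[p], sg)
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    dose <- pmax(dose + matrix(stats::rnorm(nx * ny, sd = noise_sd), nx, ny), 0)
  }
  dose_grid(dose, origin = c(xs[1], ys[1]), spacing = c(spacing, spacing))
}

#' Delivery-error specification
#'
#' Exactly one error kind: `"MU_scale"` multiplies delivered dose by
#' `1 + magnitude` (machine-output error, magnitude is a fraction, e.g.
#' `0.02` for +2%); `"DLG_shift"` widens every open leaf-pair aperture by
#' `magnitude` mm (dosimetric-leaf-gap error; each bank edge retracts by
#' `magnitude / 2`).
#'
#' @param kind `"MU_scale"` or `"DLG_shift"`.
#' @param magnitude fraction (MU) or mm (DLG); must be finite.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(kind = c("MU_scale", "DLG_shift"), magnitude) {
  kind <- match.arg(kind)
  magnitude <- as.double(magnitude)
  if (length(magnitude) != 1L || !is.finite(magnitude)) {
    stop("error_spec: magnitude must be a single finite number", call. = FALSE)
  }
  structure(list(kind = kind, magnitude = magnitude), class = "error_spec")
}

#' Apply a delivery error
#'
#' `MU_scale` applied to a dose grid scales every value by `1 + magnitude`;
#' applied to a `field_spec` it scales the segment weights and regenerates
#' the map. `DLG_shift` requires a `field_spec` (an aperture description):
#' both leaf banks retract by `magnitude / 2` and the map is regenerated.
#'
#' @param x a [dose_grid()] or [field_spec()].
#' @param err an [error_spec()].
#' @param ... for `field_spec` input, passed to [generate_vmat_dosemap()].
#' @return a [dose_grid()].
#' @export
apply_error <- function(x, err, ...) {
  stopifnot(inherits(err, "error_spec"))
  UseMethod("apply_error")
}

#' @export
apply_error.dose_grid <- function(x, err, ...) {
  if (err$kind != "MU_scale") {
    stop("apply_error: DLG_shift needs a field_spec (aperture description), not a raw grid",
         call. = FALSE)
  }
  dose_grid(x$values * (1 + err$magnitude), origin = x$origin, spacing = x$spacing)
}

#' @export
apply_error.field_spec <- function(x, err, ...) {
  generate_vmat_dosemap(perturb_field_spec(x, err), ...)
}

#' Perturb a field specification by a delivery error
#'
#' @inheritParams apply_error
#' @return a modified `field_spec`.
#' @export
perturb_field_spec <- function(x, err) {
  stopifnot(inherits(x, "field_spec"), inherits(err, "error_spec"))
  segs <- lapply(x$segments, function(s) {
    if (err$kind == "MU_scale") {
      s$weight <- s$weight * (1 + err$magnitude)
    } else {
      open <- !is.na(s$apertures[, 1])
      s$apertures[open, 1] <- s$apertures[open, 1] - err$magnitude / 2
      s$apertures[open, 2] <- s$apertures[open, 2] + err$magnitude / 2
    }
    s
  })
  field_spec(segs, penumbra_sigma = x$penumbra_sigma,
             collimator_deg = x$collimator_deg)
}

# ---- voxel phantom ---------------------------------------------------------

#' Electron-density voxel phantom
#'
#' Builds a voxel phantom for dose reconstruction. Coordinates: x lateral,
#' y longitudinal, z depth below the entrance surface (beam travels +z);
#' the X-ray focus sits on the central axis at `z = det_depth - sad`.
#'
#' * `homogeneous_water`: box, all in-contour densities 1.
#' * `cylinder`: circular cross-section in the (x, z) plane (axis along the
#'   couch direction y), density `1` inside, emulating a cylindrical
#'   polystyrene phantom.
#' * `thorax_like`: water box with a low-density slab (default 0.25,
#'   lung-like) spanning `insert_z` in depth.
#'
#' @param kind phantom kind.
#' @param lateral half-extent in x and y, mm.
#' @param thickness depth extent, mm.
#' @param spacing voxel size, mm (isotropic).
#' @param radius cylinder radius, mm (cylinder only).
#' @param insert_z depth range c(lo, hi) of the low-density slab, mm.
#' @param insert_density relative electron density of the slab.
#' @param sad source-to-axis distance, mm.
#' @param det_depth depth of the detector/measurement plane, mm.
#' @return An object of class `voxel_phantom`: density array (relative to
#'   water), contour mask, voxel coordinates, focus position.
#' @export
make_phantom <- function(kind = c("homogeneous_water", "cylinder", "thorax_like"),
                         lateral = 150, thickness = 200, spacing = 5,
                         radius = 100, insert_z = c(40, 80),
                         insert_density = 0.25, sad = 1000, det_depth = 100) {
  kind <- match.arg(kind)
  if (lateral <= 0 || thickness <= 0 || spacing <= 0) {
    stop("make_phantom: dimensions must be positive", call. = FALSE)
  }
  xs <- seq(-lateral + spacing / 2, lateral - spacing / 2, by = spacing)
  ys <- xs
  if (kind == "cylinder") thickness <- 2 * radius
  zs <- seq(spacing / 2, thickness - spacing / 2, by = spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  density <- array(1, dim = c(nx, ny, nz))
  contour <- array(TRUE, dim = c(nx, ny, nz))
  if (kind == "cylinder") {
    # axis along y at depth = radius; surface touches z = 0
    r2 <- outer(xs^2, (zs - radius)^2, "+")
    inside <- r2 <= radius^2
    for (j in seq_len(ny)) contour[, j, ] <- inside
  } else if (kind == "thorax_like") {
    in_slab <- zs >= insert_z[1] & zs <= insert_z[2]
    density[, , in_slab] <- insert_density
  }
  density[!contour] <- 0
  structure(
    list(kind = kind, density = density, contour = contour,
         x = xs, y = ys, z = zs, spacing = spacing,
         sad = sad, det_depth = det_depth,
         focus = c(0, 0, det_depth - sad)),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom> %s, %d x %d x %d voxels @ %g mm, detector plane at depth %g mm, SAD %g mm\n",
    x$kind, length(x$x), length(x$y), length(x$z), x$spacing, x$det_depth, x$sad
  ))
  invisible(x)
}

# ---- beam depth-dose model -------------------------------------------------

#' 6 MV beam depth-dose model
#'
#' Percentage depth dose (PDD) supplied analytically (exponential attenuation
#' with a build-up term and the inverse-square divergence of a point source)
#' or as a table, normalised to 1 at the reference depth. The
#' tissue-phantom-ratio curve is derived with the standard Mayneord-type
#' relation `TPR(d) = PDD(d) * ((SSD + d) / (SSD + d_ref))^2`, renormalised
#' to 1 at `d_ref`, which removes the inverse-square component of the PDD.
#'
#' Defaults (`mu = 0.0046/mm`, build-up constant 3.5 mm, `d_ref = 15 mm`)
#' give a 6 MV-like curve with maximum near 15 mm depth.
#'
#' @param pdd_table optional data.frame/matrix with columns depth (mm) and
#'   relative dose; overrides the analytic form.
#' @param mu linear attenuation coefficient, 1/mm.
#' @param buildup build-up constant, mm (0 disables build-up).
#' @param d_ref reference (normalisation) depth, mm.
#' @param ssd nominal source-surface distance used in the conversion, mm.
#' @param d_max maximum tabulated depth, mm.
#' @return An object of class `beam_model` with `pdd(d)` and `tpr(d)`
#'   interpolators (depth in mm; negative depths are rejected).
#' @export
make_beam_model <- function(pdd_table = NULL, mu = 0.0046, buildup = 3.5,
                            d_ref = 15, ssd = 900, d_max = 400) {
  depths <- seq(0, d_max, by = 1)
  # inverse-square divergence factor; ssd = Inf is the parallel-beam limit
  isq <- if (is.finite(ssd)) ((ssd + depths) / (ssd + d_ref))^2 else rep(1, length(depths))
  if (is.null(pdd_table)) {
    raw <- exp(-mu * depths) / isq
    if (buildup > 0) raw <- raw * (1 - exp(-(depths + 0.5) / buildup))
  } else {
    pdd_table <- as.matrix(pdd_table)
    raw <- stats::approx(pdd_table[, 1], pdd_table[, 2], xout = depths, rule = 2)$y
  }
  if (any(raw <= 0)) stop("make_beam_model: PDD must be positive", call. = FALSE)
  pdd <- raw / stats::approx(depths, raw, xout = d_ref)$y
  tpr_raw <- pdd * isq
  tpr <- tpr_raw / stats::approx(depths, tpr_raw, xout = d_ref)$y
  pdd_fun <- stats::approxfun(depths, pdd, rule = 2)
  tpr_fun <- stats::approxfun(depths, tpr, rule = 2)
  structure(
    list(
      energy = "6MV", ssd = ssd, d_ref = d_ref,
      depths = depths, pdd_curve = pdd, tpr_curve = tpr,
      pdd = function(d) {
        if (any(d < 0)) stop("beam_model: negative depth", call. = FALSE)
        pdd_fun(d)
      },
      tpr = function(d) {
        if (any(d < 0)) stop("beam_model: negative depth", call. = FALSE)
        tpr_fun(d)
      }
    ),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "<beam_model> %s, d_ref %g mm, SSD %g mm, TPR(100 mm) = %.3f\n",
    x$energy, x$d_ref, x$ssd, x$tpr(100)
  ))
  invisible(x)
}
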