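# 2D ion-chamber array models, area-averaged sampling and coalescence.

#' Build an ion-chamber array geometry
#'
#' Two commercial geometries are modelled:
#' * `d729`: 27 x 27 = 729 chambers on a 10 mm square grid, 5 x 5 mm^2
#'   apertures (5 mm edge-to-edge gaps), 270 x 270 mm^2 extent.
#' * `d1500`: 1405 chambers in a checkerboard — a 27 x 27 main grid (10 mm
#'   pitch) plus a 26 x 26 interstitial grid offset by (5, 5) mm — with
#'   4.4 x 4.4 mm^2 apertures and 7.07 mm centre-to-centre diagonal spacing.
#'
#' Chamber response is a uniform top-hat over the square aperture; the
#' chamber height is carried as metadata only.
#'
#' @param model `"d729"` or `"d1500"`.
#' @return An object of class `detector_array` with chamber centre
#'   coordinates (mm, isocentre at the origin), aperture side (mm), layout
#'   and extent.
#' @export
build_array <- function(model = c("d729", "d1500")) {
  model <- match.arg(model)
  main <- seq(-130, 130, by = 10)
  if (model == "d729") {
    centers <- expand.grid(x = main, y = main)
    aperture <- 5
    height <- 5
    layout <- "square_grid"
  } else {
    inter <- seq(-125, 125, by = 10)
    centers <- rbind(expand.grid(x = main, y = main),
                     expand.grid(x = inter, y = inter))
    aperture <- 4.4
    height <- 3
    layout <- "checkerboard"
  }
  structure(
    list(model = model, x = centers$x, y = centers$y,
         aperture = aperture, height = height, layout = layout,
         extent = c(270, 270)),
    class = "detector_array"
  )
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf(
    "<detector_array> %s: %d chambers (%s), %g x %g mm^2 apertures over %g x %g cm^2\n",
    x$model, length(x$x), x$layout, x$aperture, x$aperture,
    x$extent[1] / 10, x$extent[2] / 10
  ))
  invisible(x)
}

#' Number of chambers
#' @param array a `detector_array`.
#' @return integer chamber count.
#' @export
n_chambers <- function(array) length(array$x)

#' Sample a planar dose with an ion-chamber array
#'
#' Each chamber reads the mean ground-truth dose over its square aperture:
#' the quadrature is the mean of all dose-grid pixels whose centres fall
#' inside the aperture. The array may be shifted (couch moves) before
#' sampling; sample positions are the shifted chamber centres.
#'
#' @param dose a [dose_grid()]; its spacing must be finer than the chamber
#'   aperture.
#' @param array a [build_array()] geometry.
#' @param shift_mm length-2 numeric, lateral/longitudinal array shift, mm.
#' @param noise_sd optional additive Gaussian measurement noise sd (dose
#'   units), default 0; uses the current RNG state.
#' @return An object of class `measured_map`: data.frame-like list with
#'   sample positions `x`, `y` (mm), `dose`, the acquisition `shift_mm` and
#'   provenance (`model`).
#' @export
sample_dose <- function(dose, array, shift_mm = c(0, 0), noise_sd = 0) {
  stopifnot(inherits(dose, "dose_grid"), inherits(array, "detector_array"))
  if (any(dose$spacing >= array$aperture)) {
    stop("sample_dose: dose grid must be finer than the chamber aperture", call. = FALSE)
  }
  cx <- array$x + shift_mm[1]
  cy <- array$y + shift_mm[2]
  half <- array$aperture / 2
  ext <- grid_extent(dose)
  out_of_grid <- cx - half < ext$x[1] | cx + half > ext$x[2] |
    cy - half < ext$y[1] | cy + half > ext$y[2]
  if (any(out_of_grid)) {
    stop(sprintf("sample_dose: chamber aperture(s) outside dose grid (first: chamber %d at x=%g, y=%g mm)",
                 which(out_of_grid)[1], cx[which(out_of_grid)[1]], cy[which(out_of_grid)[1]]),
         call. = FALSE)
  }
  vals <- aperture_mean_cpp(dose$values, dose$origin, dose$spacing, cx, cy, half)
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  measured_map(cx, cy, vals, shift_mm = shift_mm, model = array$model)
}

measured_map <- function(x, y, dose, shift_mm = c(0, 0), model = NA_character_,
                         coalesced = FALSE) {
  structure(
    list(x = as.double(x), y = as.double(y), dose = as.double(dose),
         shift_mm = as.double(shift_mm), model = model, coalesced = coalesced),
    class = "measured_map"
  )
}

#' @export
print.measured_map <- function(x, ...) {
  cat(sprintf(
    "<measured_map>%s %d points (%s), shift (%g, %g) mm, dose [%.4g, %.4g]\n",
    if (isTRUE(x$coalesced)) " coalesced," else "",
    length(x$x), x$model, x$shift_mm[1], x$shift_mm[2],
    min(x$dose), max(x$dose)
  ))
  invisible(x)
}

#' @export
as.data.frame.measured_map <- function(x, ...) {
  data.frame(x_mm = x$x, y_mm = x$y, dose = x$dose)
}

#' Read / write a measured map as CSV
#'
#' Columns `x_mm`, `y_mm`, `dose`.
#' @param map a `measured_map`.
#' @param path file path.
#' @export
write_measured_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measured_map
#' @export
read_measured_map <- function(path) {
  df <- utils::read.csv(path)
  measured_map(df$x_mm, df$y_mm, df$dose)
}

#' Coalescence failure condition
#'
#' @description Signalled by [coalesce()] when near-coincident points of the
#' two acquisitions disagree by more than the tolerance; carries the maximum
#' discrepancy in field `max_discrepancy`.
#' @name coalescence_error
NULL

coalescence_error <- function(msg, max_discrepancy) {
  structure(
    class = c("coalescence_error", "error", "condition"),
    list(message = msg, call = NULL, max_discrepancy = max_discrepancy)
  )
}

#' Coalesce two acquisitions into one higher-resolution map
#'
#' Merges the isocentre acquisition with a couch-shifted acquisition of the
#' same array (nominally +5 mm longitudinal), doubling the sampling density
#' along the shift axis. Near-coincident points (within `position_eps`) are
#' merged by averaging; if any such pair disagrees in dose by more than
#' `tolerance`, coalescence fails with a [coalescence_error] reporting the
#' maximum discrepancy (emulating clinically failed coalescences).
#'
#' @param iso,shifted `measured_map`s from the same array model.
#' @param tolerance maximum tolerated |dose difference| on coincident points
#'   (dose units).
#' @param position_eps positional epsilon for duplicate merging, mm.
#' @return A coalesced `measured_map` with an `overlap` attribute: list with
#'   `n_merged` and `max_discrepancy`.
#' @export
coalesce <- function(iso, shifted, tolerance = Inf, position_eps = 0.1) {
  stopifnot(inherits(iso, "measured_map"), inherits(shifted, "measured_map"))
  if (!identical(iso$model, shifted$model)) {
    stop("coalesce: maps come from different array models", call. = FALSE)
  }
  x <- c(iso$x, shifted$x)
  y <- c(iso$y, shifted$y)
  d <- c(iso$dose, shifted$dose)
  # merge near-coincident points by snapping to an eps lattice
  key <- paste(round(x / position_eps), round(y / position_eps))
  grp <- match(key, unique(key))
  n_merged <- sum(duplicated(grp))
  max_disc <- 0
  if (n_merged > 0) {
    rng <- tapply(d, grp, function(v) diff(range(v)))
    max_disc <- max(rng)
    if (max_disc > tolerance) {
      stop(coalescence_error(
        sprintf("coalesce: overlapping dose difference %.4g exceeds tolerance %.4g",
                max_disc, tolerance),
        max_disc
      ))
    }
    x <- as.double(tapply(x, grp, mean))
    y <- as.double(tapply(y, grp, mean))
    d <- as.double(tapply(d, grp, mean))
  }
  out <- measured_map(x, y, d, shift_mm = c(0, 0), model = iso$model,
                      coalesced = TRUE)
  attr(out, "overlap") <- list(n_merged = n_merged, max_discrepancy = max_disc)
  out
}

#' Spatial sampling frequency of an array
#'
#' Computed geometrically from the sample-point set: points are grouped into
#' lines along the requested direction and the frequency is the reciprocal
#' of the minimum centre spacing along a line. Coalescing the isocentre and
#' +5 mm-shifted acquisitions doubles the frequency along the shift axis
#' (and, for the checkerboard array, along rows as well).
#'
#' @param array a `detector_array` or a `measured_map` (e.g. a coalesced map).
#' @param direction `"row"` (along x), `"column"` (along y) or `"diagonal"`.
#' @param coalesced for a `detector_array`: report the frequency after
#'   coalescence with a +5 mm longitudinal shift.
#' @return sampling frequency, 1/mm.
#' @export
sampling_frequency <- function(array, direction = c("row", "column", "diagonal"),
                               coalesced = FALSE) {
  direction <- match.arg(direction)
  if (inherits(array, "detector_array")) {
    x <- array$x; y <- array$y
    if (coalesced) {
      x <- c(x, x); y <- c(y, y + 5)
    }
  } else {
    x <- array$x; y <- array$y
  }
  if (direction == "diagonal") {
    u <- (x + y) / sqrt(2)
    v <- (y - x) / sqrt(2)
    x <- u; y <- v
  }
  along <- if (direction == "column") y else x
  across <- if (direction == "column") x else y
  key <- round(across, 3)
  spacings <- unlist(lapply(split(along, key), function(v) {
    if (length(v) < 2) return(NULL)
    diff(sort(v))
  }))
  spacings <- spacings[spacings > 1e-6]
  if (length(spacings) == 0) stop("sampling_frequency: no collinear point pairs", call. = FALSE)
  1 / min(spacings)
}

#' Detector fill factor
#'
#' Geometric coverage of the detector plane by sensitive chamber area.
#' `linear`: aperture side divided by the centre spacing along a row
#' (0.5 for the 729 array: 5 mm / 10 mm). `areal`: total aperture area
#' divided by the active extent. Published fill factors based on
#' lateral-response-function overlap (e.g. 0.86 for the checkerboard array)
#' use a response model that is out of scope here; only geometric coverage
#' is reported.
#'
#' @param array a `detector_array`.
#' @param definition `"linear"` or `"areal"`.
#' @param coalesced include the +5 mm-shifted second acquisition.
#' @return fraction in \[0, 1\] (capped at 1 when apertures overlap).
#' @export
fill_factor <- function(array, definition = c("linear", "areal"),
                        coalesced = FALSE) {
  definition <- match.arg(definition)
  if (definition == "linear") {
    pitch <- 1 / sampling_frequency(array, "row", coalesced = coalesced)
    return(min(1, array$aperture / pitch))
  }
  n <- n_chambers(array) * (if (coalesced) 2 else 1)
  min(1, n * array$aperture^2 / prod(array$extent))
}

# ---- lattice view & interpolation of measured maps -------------------------

# All modelled point sets live on a 5 mm lattice in either the axis frame
# (729, coalesced maps) or the 45-degree rotated frame (1500 checkerboard).
# as_lattice() picks the frame in which the points form a regular (possibly
# holed) grid; interp_map() then interpolates bilinearly in that frame,
# matching the "linear interpolation between adjacent points" behaviour of
# commercial analysis software. Cells with a missing corner give NA.

as_lattice <- function(map) {
  make <- function(x, y, rotated) {
    ux <- sort(unique(round(x, 9)))
    uy <- sort(unique(round(y, 9)))
    if (length(ux) < 2 || length(uy) < 2) return(NULL)
    dx <- diff(ux); dy <- diff(uy)
    if (max(dx) - min(dx) > 1e-6 || max(dy) - min(dy) > 1e-6) {
      # irregular level spacing: still usable if levels are lattice multiples
      sx <- min(dx); sy <- min(dy)
      if (any(abs(dx / sx - round(dx / sx)) > 1e-6) ||
          any(abs(dy / sy - round(dy / sy)) > 1e-6)) return(NULL)
      ux <- seq(ux[1], ux[length(ux)], by = sx)
      uy <- seq(uy[1], uy[length(uy)], by = sy)
    }
    ix <- match(round(x, 9), round(ux, 9))
    iy <- match(round(y, 9), round(uy, 9))
    if (anyNA(ix) || anyNA(iy)) return(NULL)
    m <- matrix(NA_real_, length(ux), length(uy))
    m[cbind(ix, iy)] <- map$dose
    # interior fill decides the frame: a checkerboard has holes between
    # lattice sites in the axis frame but a fully filled interior (diamond
    # hull) in the 45-degree frame
    ci <- seq(ceiling(length(ux) / 4), floor(3 * length(ux) / 4))
    cj <- seq(ceiling(length(uy) / 4), floor(3 * length(uy) / 4))
    center_fill <- sum(!is.na(m[ci, cj, drop = FALSE])) / (length(ci) * length(cj))
    list(ux = ux, uy = uy, values = m, rotated = rotated,
         center_fill = center_fill)
  }
  plain <- make(map$x, map$y, FALSE)
  if (!is.null(plain) && plain$center_fill > 0.99) return(plain)
  rot <- make((map$x + map$y) / sqrt(2), (map$y - map$x) / sqrt(2), TRUE)
  if (!is.null(rot) &&
      (is.null(plain) || rot$center_fill > plain$center_fill)) return(rot)
  if (!is.null(plain)) return(plain)
  stop("as_lattice: sample points do not form a regular lattice in either frame",
       call. = FALSE)
}

#' Linearly interpolate a measured map
#'
#' Bilinear interpolation in the frame (axis-aligned or 45-degree rotated)
#' in which the sample points form a regular lattice. Queries outside the
#' sampled hull, or in cells with a missing lattice site, return `NA`.
#'
#' @param map a `measured_map`.
#' @param x,y query coordinates, mm.
#' @return numeric vector of interpolated doses.
#' @export
interp_map <- function(map, x, y) {
  lat <- as_lattice(map)
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n); y <- rep_len(as.double(y), n)
  if (lat$rotated) {
    u <- (x + y) / sqrt(2); v <- (y - x) / sqrt(2)
    x <- u; y <- v
  }
  fx <- (x - lat$ux[1]) / (lat$ux[2] - lat$ux[1])
  fy <- (y - lat$uy[1]) / (lat$uy[2] - lat$uy[1])
  out <- bilinear_cpp(lat$values, fx, fy)
  out[fx < 0 | fx > length(lat$ux) - 1 | fy < 0 | fy > length(lat$uy) - 1] <- NA_real_
  out
}
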