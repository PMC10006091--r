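#' HD-MLC leaf geometry
#'
#' Leaf-pair widths and longitudinal edges of a 60-pair high-definition MLC:
#' the innermost 32 pairs are 2.5 mm wide and the outer 2 x 14 pairs are
#' 5.0 mm wide, for a 220 mm total longitudinal span centred on the axis.
#'
#' @return list with `widths` (mm, length 60), `lower`/`upper` leaf-pair edge
#'   positions (mm) and `centers` (mm).
#' @export
hdmlc_geometry <- function() {
  widths <- c(rep(5, 14), rep(2.5, 32), rep(5, 14))
  upper <- cumsum(widths) - sum(widths) / 2
  lower <- upper - widths
  list(widths = widths, lower = lower, upper = upper, centers = (lower + upper) / 2)
}

#' MLC field specification
#'
#' Describes one or more apertures (segments) of an MLC-shaped field. Each
#' segment holds per-leaf-pair tip positions along leaf travel (x) and a
#' non-negative fluence weight; the dose-map generator renders each open
#' leaf-pair strip as an erf-edged profile between the tips times a top-hat
#' over the leaf width, i.e. the leaf rectangle convolved with an isotropic
#' Gaussian penumbra kernel.
#'
#' @param segments list of segments; each a list with `apertures` (60 x 2
#'   matrix of left/right leaf-tip x positions in mm, `NA` rows = closed
#'   pair) and `weight` (>= 0).
#' @param penumbra_sigma Gaussian penumbra sigma, mm (0 = ideal top-hat edges).
#' @param collimator_deg collimator rotation, degrees.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(segments, penumbra_sigma = 3, collimator_deg = 0) {
  if (!is.list(segments) || length(segments) == 0) {
    stop("field_spec: need at least one segment", call. = FALSE)
  }
  mlc <- hdmlc_geometry()
  segments <- lapply(segments, function(s) {
    ap <- as.matrix(s$apertures)
    if (nrow(ap) != 60L || ncol(ap) != 2L) {
      stop("field_spec: apertures must be a 60 x 2 matrix", call. = FALSE)
    }
    open <- !is.na(ap[, 1]) & !is.na(ap[, 2])
    if (any(ap[open, 2] < ap[open, 1])) {
      stop("field_spec: right leaf tip must not be left of the left tip", call. = FALSE)
    }
    w <- as.double(s$weight)
    if (length(w) != 1L || !is.finite(w) || w < 0) {
      stop("field_spec: segment weight must be a single non-negative number", call. = FALSE)
    }
    list(apertures = ap, weight = w)
  })
  if (!is.finite(penumbra_sigma) || penumbra_sigma < 0) {
    stop("field_spec: penumbra_sigma must be >= 0", call. = FALSE)
  }
  structure(
    list(segments = segments, penumbra_sigma = as.double(penumbra_sigma),
         collimator_deg = as.double(collimator_deg), mlc = mlc),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  n_open <- vapply(x$segments, function(s) sum(!is.na(s$apertures[, 1])), 0L)
  cat(sprintf(
    "<field_spec> %d segment(s), open leaf pairs %s, penumbra sigma %g mm, collimator %g deg\n",
    length(x$segments), paste(n_open, collapse = "/"),
    x$penumbra_sigma, x$collimator_deg
  ))
  invisible(x)
}

#' Rectangular single-segment field
#'
#' Convenience constructor: all leaf pairs whose strip intersects the field
#' open from `-size[1]/2` to `size[1]/2` in x, field limited to `size[2]` in y.
#'
#' @param size field size c(x, y), mm.
#' @param weight segment fluence weight.
#' @inheritParams field_spec
#' @return a `field_spec`.
#' @export
rectangular_field <- function(size = c(100, 100), weight = 1,
                              penumbra_sigma = 3, collimator_deg = 0) {
  mlc <- hdmlc_geometry()
  ap <- matrix(NA_real_, 60, 2)
  sel <- mlc$upper > -size[2] / 2 & mlc$lower < size[2] / 2
  ap[sel, 1] <- -size[1] / 2
  ap[sel, 2] <- size[1] / 2
  field_spec(list(list(apertures = ap, weight = weight)),
             penumbra_sigma = penumbra_sigma, collimator_deg = collimator_deg)
}

#' Random VMAT-like field specification
#'
#' Draws a modulated multi-segment field emulating the leaf-width-scale
#' structure of a VMAT control-point aperture: per-pair tip positions follow
#' a smoothed random walk around a random field outline, segments carry
#' random weights. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param n_segments number of aperture segments.
#' @param field_size approximate c(x, y) field dimensions, mm.
#' @param modulation sd of the smoothed per-pair tip perturbations, mm.
#' @inheritParams field_spec
#' @return a `field_spec`.
#' @export
random_field_spec <- function(n_segments = 2, field_size = c(120, 140),
                              modulation = 12, penumbra_sigma = 3,
                              collimator_deg = 10) {
  mlc <- hdmlc_geometry()
  sel <- mlc$upper > -field_size[2] / 2 & mlc$lower < field_size[2] / 2
  n_open <- sum(sel)
  smooth_walk <- function(n, sd) {
    z <- stats::rnorm(n + 4, sd = sd)
    stats::filter(z, rep(1 / 5, 5), sides = 2)[3:(n + 2)]
  }
  segments <- lapply(seq_len(n_segments), function(k) {
    half <- field_size[1] / 2
    left <- pmin(-5, -half + smooth_walk(n_open, modulation))
    right <- pmax(5, half + smooth_walk(n_open, modulation))
    ap <- matrix(NA_real_, 60, 2)
    ap[sel, 1] <- left
    ap[sel, 2] <- right
    list(apertures = ap, weight = stats::runif(1, 0.5, 1.5))
  })
  field_spec(segments, penumbra_sigma = penumbra_sigma,
             collimator_deg = collimator_deg)
}
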