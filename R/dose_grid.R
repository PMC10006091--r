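#' Planar dose grid
#'
#' A regular 2D dose distribution in the detector/measurement plane.
#' Values are stored in a matrix whose first index runs along the lateral
#' (x) axis and whose second index runs along the longitudinal (y, couch
#' travel) axis; coordinates are in millimetres with the beam central axis
#' at (0, 0).
#'
#' @param values numeric matrix of dose values (Gy or relative), `values[i, j]`
#'   at `x = origin[1] + (i-1) * spacing[1]`, `y = origin[2] + (j-1) * spacing[2]`.
#' @param origin length-2 numeric, mm coordinate of the first grid node.
#' @param spacing length-2 positive numeric, mm grid step per axis.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0), spacing = c(1, 1)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  origin <- as.double(origin)
  spacing <- as.double(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(origin) == 1L) origin <- rep(origin, 2L)
  g <- structure(
    list(values = values, origin = origin, spacing = spacing),
    class = "dose_grid"
  )
  validate_dose_grid(g)
  g
}

validate_dose_grid <- function(g) {
  stopifnot(is.matrix(g$values), length(g$origin) == 2L, length(g$spacing) == 2L)
  if (any(!is.finite(g$spacing)) || any(g$spacing <= 0)) {
    stop("dose_grid: spacing must be positive and finite", call. = FALSE)
  }
  if (anyNA(g$values) || any(g$values < 0)) {
    stop("dose_grid: values must be non-negative and non-missing", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d, spacing %g x %g mm, x [%g, %g] mm, y [%g, %g] mm, max %.4g\n",
    d[1], d[2], x$spacing[1], x$spacing[2],
    x$origin[1], x$origin[1] + (d[1] - 1) * x$spacing[1],
    x$origin[2], x$origin[2] + (d[2] - 1) * x$spacing[2],
    max(x$values)
  ))
  invisible(x)
}

#' Grid node coordinates
#'
#' @param g a `dose_grid`.
#' @return numeric vector of x (lateral) or y (longitudinal) node positions, mm.
#' @export
grid_x <- function(g) g$origin[1] + (seq_len(nrow(g$values)) - 1) * g$spacing[1]

#' @rdname grid_x
#' @export
grid_y <- function(g) g$origin[2] + (seq_len(ncol(g$values)) - 1) * g$spacing[2]

grid_extent <- function(g) {
  d <- dim(g$values)
  list(
    x = c(g$origin[1], g$origin[1] + (d[1] - 1) * g$spacing[1]),
    y = c(g$origin[2], g$origin[2] + (d[2] - 1) * g$spacing[2])
  )
}

#' Bilinear interpolation of a dose grid
#'
#' Points outside the grid return `NA` unless `rule = "zero"`.
#'
#' @param g a `dose_grid`.
#' @param x,y query coordinates, mm (recycled to common length).
#' @param rule `"na"` or `"zero"` for out-of-extent queries.
#' @return numeric vector of interpolated dose values.
#' @export
interp_grid <- function(g, x, y, rule = c("na", "zero")) {
  rule <- match.arg(rule)
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n)
  y <- rep_len(as.double(y), n)
  fx <- (x - g$origin[1]) / g$spacing[1]
  fy <- (y - g$origin[2]) / g$spacing[2]
  nx <- nrow(g$values); ny <- ncol(g$values)
  out <- bilinear_cpp(g$values, fx, fy)
  bad <- fx < 0 | fx > nx - 1 | fy < 0 | fy > ny - 1
  out[bad] <- if (rule == "zero") 0 else NA_real_
  out
}

#' Resample a dose grid onto a new regular grid
#'
#' Bilinear resampling; used e.g. to mimic a TPS calculation grid (2.5 mm)
#' from a finer generated map.
#'
#' @param g a `dose_grid`.
#' @param spacing new spacing, mm (scalar or length 2).
#' @param extent optional list with `x`, `y` ranges (mm); defaults to the
#'   largest aligned grid inside `g`.
#' @return a `dose_grid`.
#' @export
resample_grid <- function(g, spacing, extent = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (is.null(extent)) extent <- grid_extent(g)
  xs <- seq(extent$x[1], extent$x[2], by = spacing[1])
  ys <- seq(extent$y[1], extent$y[2], by = spacing[2])
  vals <- interp_grid(g, rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  if (anyNA(vals)) stop("resample_grid: requested extent outside source grid", call. = FALSE)
  dose_grid(matrix(vals, nrow = length(xs)), origin = c(xs[1], ys[1]), spacing = spacing)
}

# ---- plain-text grid format ------------------------------------------------
# Header lines: "nx <int>", "ny <int>", "origin_mm <x> <y>", "spacing_mm <dx> <dy>"
# followed by ny lines of nx values each (one line per y row, x varying along
# the line). Values are written with 17 significant digits so that the
# write -> read round trip is bit-exact.

#' Read / write the plain-text dose-grid format
#'
#' The format is four header lines (`nx`, `ny`, `origin_mm`, `spacing_mm`)
#' followed by `ny` whitespace-separated rows of `nx` values (row-major along
#' x). Round trips are bit-exact.
#'
#' @param path file path.
#' @return `read_dose_grid` returns a `dose_grid`; `write_dose_grid` returns
#'   `path` invisibly.
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L) stop("dose grid file too short: ", path, call. = FALSE)
  hdr <- function(key, line, n) {
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) != n + 1L || parts[1] != key) {
      stop(sprintf("malformed dose grid header, expected '%s': %s", key, line), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) stop("non-numeric dose grid header value: ", line, call. = FALSE)
    v
  }
  nx <- hdr("nx", lines[1], 1); ny <- hdr("ny", lines[2], 1)
  origin <- hdr("origin_mm", lines[3], 2)
  spacing <- hdr("spacing_mm", lines[4], 2)
  if (any(spacing <= 0)) stop("dose grid header: spacing must be > 0", call. = FALSE)
  vals <- scan(text = paste(lines[-(1:4)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nx * ny) {
    stop(sprintf("dose grid payload has %d values, expected %d", length(vals), nx * ny),
         call. = FALSE)
  }
  # payload is one line per y row -> fill x fastest
  dose_grid(matrix(vals, nrow = nx, ncol = ny), origin = origin, spacing = spacing)
}

#' @rdname read_dose_grid
#' @param g a `dose_grid` to write.
#' @export
write_dose_grid <- function(g, path) {
  validate_dose_grid(g)
  d <- dim(g$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("nx", d[1]), paste("ny", d[2]),
    paste("origin_mm", fmt17(g$origin[1]), fmt17(g$origin[2])),
    paste("spacing_mm", fmt17(g$spacing[1]), fmt17(g$spacing[2]))
  ), con)
  for (j in seq_len(d[2])) {
    writeLines(paste(fmt17(g$values[, j]), collapse = " "), con)
  }
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)
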