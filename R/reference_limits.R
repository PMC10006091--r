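#' Bundled reference QA limits from a clinical VMAT program
#'
#' Action-limit spans, lower action limits, lower control limits and
#' process capability indices published by a 126-plan clinical VMAT QA
#' program running both array models under standard-acquisition (SA) and
#' coalescence procedures at four tolerance criteria. Bundled as reference
#' input for worked examples and arithmetic cross-checks (e.g.
#' `LAL = 100 - delta_a / 2`); the underlying patient measurements are not
#' public, so these values are inputs, not outputs, of this package.
#'
#' @return data.frame with columns `criteria`, `detector`, `procedure`,
#'   `delta_a` (%), `lal` (%), `lcl` (%), and `cpk` (coalescence rows only;
#'   assessed against the SA-derived action limits).
#' @export
reference_qa_limits <- function() {
  crit <- c("3%/2mm", "2%/2mm", "2%/1mm", "1%/1mm")
  rows <- rbind(
    data.frame(criteria = crit, detector = "d729", procedure = "coalescence",
               delta_a = c(33.74, 64.86, 106.10, 193.00),
               lal = c(83.13, 67.57, 46.93, 3.40),
               lcl = c(84.24, 71.38, 57.31, 34.80),
               cpk = c(0.79, 0.76, 1.10, 1.34)),
    data.frame(criteria = crit, detector = "d729", procedure = "SA",
               delta_a = c(38.02, 67.38, 117.99, 195.56),
               lal = c(80.99, 66.31, 41.00, 2.22),
               lcl = c(82.92, 71.01, 55.78, 32.55),
               cpk = NA_real_),
    data.frame(criteria = crit, detector = "d1500", procedure = "coalescence",
               delta_a = c(12.57, 28.46, 71.14, 125.16),
               lal = c(93.58, 85.80, 64.43, 37.47),
               lcl = c(94.25, 86.10, 67.13, 41.39),
               cpk = c(0.94, 1.42, 1.19, 1.60)),
    data.frame(criteria = crit, detector = "d1500", procedure = "SA",
               delta_a = c(22.47, 47.04, 102.80, 183.93),
               lal = c(88.77, 76.48, 48.60, 8.03),
               lcl = c(88.89, 77.52, 56.58, 32.79),
               cpk = NA_real_)
  )
  rows
}
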