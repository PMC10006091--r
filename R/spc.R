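# Statistical process control and process capability analysis of percent-
# gamma QA series: individuals / moving-range charts, action limits, Cpk.

#' QA pass-rate series
#'
#' An ordered series of percent-gamma values, one per plan, in acquisition
#' order (control charts are order-sensitive).
#'
#' @param x numeric vector of percent-gamma values in \[0, 100\].
#' @param detector,procedure,criteria optional cohort labels.
#' @return An object of class `qa_series`.
#' @export
qa_series <- function(x, detector = NA_character_, procedure = NA_character_,
                      criteria = NA_character_) {
  x <- as.double(x)
  if (anyNA(x) || any(x < 0 | x > 100)) {
    stop("qa_series: values must be in [0, 100] and non-missing", call. = FALSE)
  }
  structure(list(x = x, detector = detector, procedure = procedure,
                 criteria = criteria),
            class = "qa_series")
}

series_values <- function(series) {
  if (inherits(series, "qa_series")) series$x else as.double(series)
}

#' @export
print.qa_series <- function(x, ...) {
  cat(sprintf("<qa_series> n = %d (%s / %s / %s), mean %.2f, sd %.2f\n",
              length(x$x), x$detector, x$procedure, x$criteria,
              mean(x$x), stats::sd(x$x)))
  invisible(x)
}

#' Average moving range
#'
#' Mean of the absolute differences of consecutive values:
#' `sum(|x_i - x_{i-1}|, i = 2..n) / (n - 1)`.
#'
#' @param series a [qa_series()] or numeric vector (n >= 2).
#' @return the average moving range.
#' @export
moving_range <- function(series) {
  x <- series_values(series)
  if (length(x) < 2) stop("moving_range: need at least 2 points", call. = FALSE)
  mean(abs(diff(x)))
}

#' Individuals control chart (x chart)
#'
#' Centre line `CL = mean(x)` and lower control limit
#' `LCL = CL - 2.66 * mRbar`, both computed on the first `baseline_n`
#' (in-control) points; every point of the full series below the LCL is
#' flagged. The percent-gamma quality characteristic is bounded above by
#' 100, so no upper control limit is meaningful.
#'
#' @param series a [qa_series()] or numeric vector.
#' @param baseline_n number of initial points used to set the limits
#'   (default 20, capped at the series length; >= 2).
#' @return An object of class `control_chart`: `cl`, `mrbar`, `lcl`,
#'   `baseline_n`, `flagged` (indices with x < LCL), `moving_ranges`.
#' @export
control_limits <- function(series, baseline_n = 20) {
  x <- series_values(series)
  if (baseline_n > length(x)) {
    stop("control_limits: baseline_n exceeds the series length", call. = FALSE)
  }
  if (baseline_n < 2) stop("control_limits: baseline_n must be >= 2", call. = FALSE)
  base <- x[seq_len(baseline_n)]
  mrbar <- moving_range(base)
  cl <- mean(base)
  lcl <- cl - 2.66 * mrbar
  structure(
    list(cl = cl, mrbar = mrbar, lcl = lcl, baseline_n = baseline_n,
         x = x, flagged = which(x < lcl), moving_ranges = abs(diff(x))),
    class = "control_chart"
  )
}

#' @export
print.control_chart <- function(x, ...) {
  cat(sprintf("<control_chart> n = %d, CL %.2f, mRbar %.2f, LCL %.2f, %d flagged\n",
              length(x$x), x$cl, x$mrbar, x$lcl, length(x$flagged)))
  invisible(x)
}

#' Out-of-control summary of a control chart
#'
#' @param chart a [control_limits()] result.
#' @return list with `n`, `n_flagged` and `percent` (two decimals,
#'   half-away-from-zero).
#' @export
flag_summary <- function(chart) {
  stopifnot(inherits(chart, "control_chart"))
  n <- length(chart$x)
  k <- length(chart$flagged)
  list(n = n, n_flagged = k, percent = round_half_away(100 * k / n, 2))
}

#' Action limits from process performance
#'
#' `dA = beta * sqrt((mean(x) - T)^2 + sigma^2)` with `sigma` the sample
#' standard deviation of the series, and `LAL = T - dA / 2`; the upper
#' action limit is fixed at 100 for percent-gamma (T = 100).
#'
#' @param series a [qa_series()] or numeric vector (n >= 2).
#' @param beta clinical-impact multiplier (default 4).
#' @param target process target T (default 100, the percent-gamma maximum).
#' @return list with `delta_a`, `lal`, `ual` (= target), `beta`, `target`,
#'   `sigma` and `mean`.
#' @export
action_limits <- function(series, beta = 4, target = 100) {
  x <- series_values(series)
  if (length(x) < 2) stop("action_limits: need at least 2 points", call. = FALSE)
  sigma <- stats::sd(x)
  delta_a <- beta * sqrt((mean(x) - target)^2 + sigma^2)
  list(delta_a = delta_a, lal = lal_from_delta(delta_a, target), ual = target,
       beta = beta, target = target, sigma = sigma, mean = mean(x))
}

#' Lower action limit from an action-limit span
#'
#' `LAL = T - dA / 2`.
#'
#' @param delta_a action-limit span (UAL - LAL).
#' @param target process target (default 100).
#' @return the lower action limit.
#' @export
lal_from_delta <- function(delta_a, target = 100) target - delta_a / 2

#' Process capability index Cpk
#'
#' One-sided capability indices against the action limits:
#' `Cpl = (mean - LAL) / (6 (1 - P_x) s)` and
#' `Cpu = (UAL - mean) / (6 P_x s)`, with `s` the sample SD and `P_x` the
#' probability of `x <= mean(x)`, estimated by default as the empirical
#' proportion (a normal-theory value of 0.5 is selectable).
#'
#' For a percent-gamma quality characteristic the upper action limit
#' coincides with the process target (UAL = T = 100), so the upper margin is
#' not a capability defect — being close to 100% is the goal. The reported
#' `cpk` is therefore the lower index Cpl (the convention for this QA
#' statistic); the two-sided `min(Cpl, Cpu)` is kept in `cpk_min`.
#'
#' @param series a [qa_series()] or numeric vector (n >= 2, s > 0).
#' @param lal,ual lower/upper action limits (percent).
#' @param p_x `"empirical"` or `"normal"` (0.5).
#' @return An object of class `capability_result`: `cpk` (= Cpl), `cpk_min`
#'   (= min(Cpl, Cpu)), `cpl`, `cpu`, `p_x`, `s`, `mean`, `lal`, `ual`,
#'   `p_x_method`.
#' @export
cpk <- function(series, lal, ual = 100, p_x = c("empirical", "normal")) {
  p_x <- match.arg(p_x)
  x <- series_values(series)
  if (length(x) < 2) stop("cpk: need at least 2 points", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("cpk: zero standard deviation, capability undefined", call. = FALSE)
  m <- mean(x)
  px <- if (p_x == "empirical") mean(x <= m) else 0.5
  cpl <- (m - lal) / (6 * (1 - px) * s)
  cpu <- (ual - m) / (6 * px * s)
  structure(
    list(cpk = cpl, cpk_min = min(cpl, cpu), cpl = cpl, cpu = cpu, p_x = px,
         s = s, mean = m, lal = lal, ual = ual, p_x_method = p_x),
    class = "capability_result"
  )
}

#' @export
print.capability_result <- function(x, ...) {
  cat(sprintf("<capability_result> Cpk %.2f (Cpl %.2f, Cpu %.2f), P_x %.2f (%s), s %.2f\n",
              x$cpk, x$cpl, x$cpu, x$p_x, x$p_x_method, x$s))
  invisible(x)
}

#' Drop out-of-control points before capability analysis
#'
#' Single pass: removes the points below the chart's LCL (no iteration).
#'
#' @param series a [qa_series()] or numeric vector.
#' @param chart a [control_limits()] result for the same series.
#' @return a `qa_series` without the flagged points.
#' @export
remove_out_of_control <- function(series, chart) {
  x <- series_values(series)
  stopifnot(inherits(chart, "control_chart"), length(x) == length(chart$x))
  keep <- setdiff(seq_along(x), chart$flagged)
  lab <- if (inherits(series, "qa_series")) series else qa_series(x)
  qa_series(x[keep], lab$detector, lab$procedure, lab$criteria)
}

#' Paired comparison of two QA cohorts
#'
#' Normality of both cohorts is checked with Shapiro-Wilk and
#' Kolmogorov-Smirnov tests; if both cohorts are consistent with normality
#' (all p > alpha) a paired t-test is used, otherwise the Wilcoxon
#' signed-rank test. Dispersion is reported as the inter-quartile range
#' with the linear-interpolation (type-7) quartile convention.
#'
#' @param a,b paired [qa_series()] or numeric vectors of equal length.
#' @param alpha significance level (two-tailed, default 0.05).
#' @return An object of class `cohort_comparison`: test name, `p_value`,
#'   `significant`, per-cohort mean/median/IQR, and the normality p-values.
#' @export
compare_cohorts <- function(a, b, alpha = 0.05) {
  xa <- series_values(a); xb <- series_values(b)
  if (length(xa) != length(xb)) {
    stop("compare_cohorts: cohorts must be paired (equal length)", call. = FALSE)
  }
  norm_p <- function(v) {
    sw <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    ks <- suppressWarnings(stats::ks.test(scale(v), "pnorm")$p.value)
    c(shapiro = sw, ks = ks)
  }
  na <- norm_p(xa); nb <- norm_p(xb)
  normal <- all(c(na, nb) > alpha, na.rm = TRUE)
  d <- xb - xa
  if (all(d == 0)) {
    test <- "paired t-test"; p <- 1
  } else if (normal && stats::sd(d) > 0) {
    test <- "paired t-test"
    p <- stats::t.test(xb, xa, paired = TRUE)$p.value
  } else {
    # includes constant non-zero shifts, where the t statistic is undefined
    test <- "Wilcoxon signed-rank"
    p <- suppressWarnings(stats::wilcox.test(xb, xa, paired = TRUE,
                                             exact = FALSE))$p.value
  }
  iqr7 <- function(v) unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7)))
  structure(
    list(test = test, p_value = p, significant = p < alpha, alpha = alpha,
         normality_p = rbind(a = na, b = nb),
         summary = data.frame(
           cohort = c("a", "b"),
           mean = c(mean(xa), mean(xb)),
           median = c(stats::median(xa), stats::median(xb)),
           iqr = c(iqr7(xa), iqr7(xb))
         ),
         quartile_rule = "type-7 (linear interpolation)"),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s, p = %.4g (%s at alpha = %g)\n",
              x$test, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Table-style rounding (`round()` in R rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
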