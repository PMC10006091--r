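# Error-detection sensitivity: delta-gamma between no-error and induced-
# error evaluations, and ROC/AUC separation of error-injected QA results.

#' Gamma pass-rate change under an induced error
#'
#' `delta_gamma = gamma_NE - gamma_IE` (percent points). A positive value
#' means the induced error lowered the pass rate, i.e. the error is
#' detected; zero or negative values are undetected (induced-error
#' behaviour can raise the pass rate case-specifically).
#'
#' @param gamma_ne,gamma_ie percent-gamma pass rates in \[0, 100\].
#' @return list with `delta_gamma` and logical `detected`.
#' @export
delta_gamma <- function(gamma_ne, gamma_ie) {
  stopifnot(all(gamma_ne >= 0 & gamma_ne <= 100),
            all(gamma_ie >= 0 & gamma_ie <= 100))
  d <- gamma_ne - gamma_ie
  list(delta_gamma = d, detected = d > 0)
}

#' ROC curve and AUC for error detection
#'
#' Score direction: a lower percent-gamma value is more "error-like", so a
#' case is called an error when its pass rate falls at or below the
#' threshold. The curve sweeps all thresholds; the AUC (trapezoid rule) is
#' identical to the rank statistic `U / (n1 * n2)` with half-credit for
#' ties. The p-value is from the two-sample Wilcoxon rank-sum test
#' (a paired signed-rank alternative is selectable).
#'
#' @param control percent-gamma values of the unmodified (no-error) group.
#' @param test percent-gamma values of the error-induced group.
#' @param paired use the paired signed-rank test for the p-value.
#' @return An object of class `roc_result`: `curve` (data.frame `fpr`,
#'   `tpr`), `auc`, `p_value`, group sizes.
#' @export
roc_auc <- function(control, test, paired = FALSE) {
  control <- as.double(control); test <- as.double(test)
  if (length(control) == 0 || length(test) == 0) {
    stop("roc_auc: both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(control, test))) == 1L &&
      (length(control) == 1L || length(test) == 1L)) {
    warning("roc_auc: degenerate groups (all-identical values)")
  }
  thr <- sort(unique(c(control, test)))
  tpr <- c(0, vapply(thr, function(t) mean(test <= t), 0.0))
  fpr <- c(0, vapply(thr, function(t) mean(control <= t), 0.0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  p <- if (paired) {
    suppressWarnings(stats::wilcox.test(test, control, paired = TRUE))$p.value
  } else {
    suppressWarnings(stats::wilcox.test(test, control))$p.value
  }
  structure(
    list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc, p_value = p,
         n_control = length(control), n_test = length(test),
         score_direction = "lower percent-gamma is more error-like"),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (n = %d control vs %d test), p = %.4g\n",
              x$auc, x$n_control, x$n_test, x$p_value))
  invisible(x)
}

#' Seeded error-injection sensitivity study
#'
#' For each of `n_plans` synthetic VMAT plans: generates a modulated field,
#' uses its dose map resampled to a TPS-like 2.5 mm grid as the calculated
#' reference, measures the delivered map with both arrays under both
#' acquisition procedures (standard and +5 mm-coalesced), and evaluates
#' percent-gamma against the reference for the no-error delivery and for
#' each induced error. Emits per-plan sensitivity records
#' (`gamma_NE`, `gamma_IE`, `delta_gamma`) and a ROC per scenario
#' (error x detector x procedure x criteria) with the no-error pass rates
#' as the control group.
#'
#' @param n_plans number of synthetic plans (default 8).
#' @param errors named list of [error_spec()]s (default +1 mm DLG widening
#'   and +2% MU scaling).
#' @param detectors character subset of `c("d729", "d1500")`.
#' @param procedures character subset of `c("SA", "coalescence")`.
#' @param criteria list of [gamma_criteria()] (default 3%/2 mm global and
#'   local, and the strictest 1%/1 mm global).
#' @param seed integer seed governing all randomness.
#' @param noise_sd measurement noise sd as a fraction of the plateau dose.
#' @param coalescence_tolerance dose tolerance for [coalesce()]; failures
#'   are logged and the affected plan/scenario excluded.
#' @return An object of class `sensitivity_study`: `records` data.frame,
#'   `roc` (named list of [roc_auc()] results), `n_coalescence_failures`.
#' @export
run_error_study <- function(n_plans = 8,
                            errors = list(DLG = error_spec("DLG_shift", 1),
                                          MU = error_spec("MU_scale", 0.02)),
                            detectors = c("d729", "d1500"),
                            procedures = c("SA", "coalescence"),
                            criteria = list(gamma_criteria(3, 2, "global"),
                                            gamma_criteria(3, 2, "local"),
                                            gamma_criteria(1, 1, "global")),
                            seed = 1, noise_sd = 0.005,
                            coalescence_tolerance = Inf) {
  set.seed(as.integer(seed))
  arrays <- lapply(stats::setNames(detectors, detectors), build_array)
  crit_names <- vapply(criteria, format_criteria, "")
  records <- list()
  n_fail <- 0L
  for (plan in seq_len(n_plans)) {
    spec <- random_field_spec()
    truth <- generate_vmat_dosemap(spec)
    reference <- resample_grid(truth, 2.5, extent = list(x = c(-150, 150), y = c(-150, 150)))
    doses <- c(list(NE = truth),
               lapply(errors, function(e) {
                 # dose is linear in the segment weights, so an MU error can
                 # scale the rendered grid directly; DLG needs regeneration
                 if (e$kind == "MU_scale") apply_error(truth, e)
                 else apply_error(spec, e)
               }))
    plateau <- max(truth$values)
    for (det in detectors) {
      for (proc in procedures) {
        maps <- lapply(doses, function(dz) {
          iso <- sample_dose(dz, arrays[[det]], c(0, 0), noise_sd = noise_sd * plateau)
          if (proc == "SA") return(iso)
          sh <- sample_dose(dz, arrays[[det]], c(0, 5), noise_sd = noise_sd * plateau)
          tryCatch(coalesce(iso, sh, tolerance = coalescence_tolerance),
                   coalescence_error = function(e) NULL)
        })
        if (any(vapply(maps, is.null, TRUE))) {
          n_fail <- n_fail + sum(vapply(maps, is.null, TRUE))
          next
        }
        for (ci in seq_along(criteria)) {
          rates <- vapply(maps, function(m) {
            pass_rate(gamma_map(reference, m, criteria[[ci]]))
          }, 0.0)
          for (err in names(errors)) {
            records[[length(records) + 1L]] <- data.frame(
              plan = plan, detector = det, procedure = proc,
              criteria = crit_names[ci], error = err,
              gamma_ne = rates[["NE"]], gamma_ie = rates[[err]],
              delta_gamma = rates[["NE"]] - rates[[err]]
            )
          }
        }
      }
    }
  }
  records <- do.call(rbind, records)
  roc <- list()
  for (err in unique(records$error)) {
    for (det in unique(records$detector)) {
      for (proc in unique(records$procedure)) {
        for (cn in unique(records$criteria)) {
          sel <- records$error == err & records$detector == det &
            records$procedure == proc & records$criteria == cn
          if (!any(sel)) next
          key <- paste(err, det, proc, cn, sep = " | ")
          roc[[key]] <- roc_auc(records$gamma_ne[sel], records$gamma_ie[sel])
        }
      }
    }
  }
  structure(
    list(records = records, roc = roc, n_coalescence_failures = n_fail,
         seed = seed),
    class = "sensitivity_study"
  )
}

#' @export
print.sensitivity_study <- function(x, ...) {
  cat(sprintf("<sensitivity_study> %d records, %d ROC scenarios, %d coalescence failure(s)\n",
              nrow(x$records), length(x$roc), x$n_coalescence_failures))
  aucs <- vapply(x$roc, function(r) r$auc, 0.0)
  print(round(aucs, 3))
  invisible(x)
}
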