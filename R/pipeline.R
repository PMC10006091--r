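# End-to-end study orchestration: generate -> sample -> coalesce ->
# gamma -> SPC/PCA -> sensitivity -> reconstruction demo, behind a single
# validated config with one seed.

#' Study configuration
#'
#' Builds and validates the configuration of a full QA study. All
#' randomness is governed by `seed`; each pipeline stage derives its own
#' sub-seed from it with a fixed per-stage offset, so adding or reordering
#' stages does not change the others' draws.
#'
#' @param n_plans number of synthetic plans in the QA cohort.
#' @param detectors subset of `c("d729", "d1500")`.
#' @param procedures subset of `c("SA", "coalescence")`.
#' @param spc_dd,spc_dta parallel vectors of tolerance criteria for the
#'   SPC/PCA stage (default the four standard global criteria 3%/2mm,
#'   2%/2mm, 2%/1mm, 1%/1mm).
#' @param errors named list of [error_spec()]s for the sensitivity stage.
#' @param n_error_plans plans in the sensitivity stage (default
#'   `min(8, n_plans)`).
#' @param beta,target action-limit parameters (defaults 4 and 100%).
#' @param baseline_n control-chart baseline size; default `min(20, n_plans)`.
#' @param noise_sd measurement noise sd as a fraction of the plateau dose.
#' @param coalescence_tolerance dose tolerance passed to [coalesce()].
#' @param seed integer master seed.
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(n_plans = 8,
                         detectors = c("d729", "d1500"),
                         procedures = c("SA", "coalescence"),
                         spc_dd = c(3, 2, 2, 1), spc_dta = c(2, 2, 1, 1),
                         errors = list(DLG = error_spec("DLG_shift", 1),
                                       MU = error_spec("MU_scale", 0.02)),
                         n_error_plans = NULL,
                         beta = 4, target = 100,
                         baseline_n = NULL,
                         noise_sd = 0.005,
                         coalescence_tolerance = Inf,
                         seed = 1) {
  if (is.null(baseline_n)) baseline_n <- min(20, n_plans)
  if (is.null(n_error_plans)) n_error_plans <- min(8, n_plans)
  cfg <- structure(
    list(n_plans = as.integer(n_plans), detectors = detectors,
         procedures = procedures, spc_dd = spc_dd, spc_dta = spc_dta,
         errors = errors, n_error_plans = as.integer(n_error_plans),
         beta = beta, target = target, baseline_n = as.integer(baseline_n),
         noise_sd = noise_sd, coalescence_tolerance = coalescence_tolerance,
         seed = as.integer(seed)),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop("study_config: ", msg, call. = FALSE)
  ok(cfg$n_plans >= 2, "n_plans must be >= 2")
  ok(all(cfg$detectors %in% c("d729", "d1500")) && length(cfg$detectors) > 0,
     "unknown detector model")
  ok(all(cfg$procedures %in% c("SA", "coalescence")) && length(cfg$procedures) > 0,
     "unknown procedure")
  ok(length(cfg$spc_dd) == length(cfg$spc_dta) && all(cfg$spc_dd > 0) && all(cfg$spc_dta > 0),
     "spc_dd/spc_dta must be matched positive vectors")
  ok(cfg$baseline_n >= 2 && cfg$baseline_n <= cfg$n_plans,
     "baseline_n must be in [2, n_plans]")
  ok(cfg$n_error_plans >= 2 && cfg$n_error_plans <= cfg$n_plans,
     "n_error_plans must be in [2, n_plans]")
  ok(all(vapply(cfg$errors, inherits, TRUE, "error_spec")),
     "errors must be error_spec objects")
  ok(cfg$beta > 0 && cfg$noise_sd >= 0, "beta must be > 0 and noise_sd >= 0")
  invisible(cfg)
}

# fixed per-stage offsets; kept below 2^31 after combination
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, sensitivity = 202L, reconstruction = 303L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_study_config` returns a validated `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$errors)) {
    raw$errors <- lapply(raw$errors, function(e) error_spec(e$kind, e$magnitude))
  }
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param cfg a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$errors <- lapply(out$errors, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full QA study
#'
#' Deterministic for a fixed config: (1) generates the synthetic plan
#' cohort and measures it with every detector/procedure combination;
#' (2) evaluates percent-gamma series at the SPC criteria and derives
#' control charts, action limits, capability indices (coalescence cohorts
#' assessed against the paired SA cohort's action limits, out-of-control
#' cases removed in a single pass) and paired cohort comparisons;
#' (3) runs the error-injection sensitivity stage with ROC summaries;
#' (4) reconstructs a demonstration volume for the first plan and compares
#' D50 across detector resolutions; (5) extracts profile comparisons.
#' Coalescence failures are logged and the run continues.
#'
#' @param config a [study_config()].
#' @param verbose print per-stage progress lines.
#' @return An object of class `qa_study`: `config`, `series` (per-cohort
#'   pass-rate tables), `spc` (chart/limit/capability tables),
#'   `comparisons`, `sensitivity`, `reconstruction`, `profiles`.
#' @export
run_study <- function(config = study_config(), verbose = interactive()) {
  validate_study_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  arrays <- lapply(stats::setNames(config$detectors, config$detectors), build_array)
  crits <- mapply(function(dd, dta) gamma_criteria(dd, dta, "global"),
                  config$spc_dd, config$spc_dta, SIMPLIFY = FALSE)
  crit_names <- vapply(crits, format_criteria, "")

  # ---- stage 1+2: cohort generation and gamma series -----------------------
  set.seed(stage_seed(config$seed, "cohort"))
  say("stage cohort: %d plans, %d detector(s), %d procedure(s), %d criteria",
      config$n_plans, length(config$detectors), length(config$procedures),
      length(crits))
  series_rows <- list()
  n_fail <- 0L
  first_plan <- NULL
  for (plan in seq_len(config$n_plans)) {
    spec <- random_field_spec()
    truth <- generate_vmat_dosemap(spec)
    reference <- resample_grid(truth, 2.5,
                               extent = list(x = c(-150, 150), y = c(-150, 150)))
    plateau <- max(truth$values)
    if (plan == 1L) first_plan <- list(spec = spec, truth = truth, reference = reference)
    for (det in config$detectors) {
      iso <- sample_dose(truth, arrays[[det]], c(0, 0),
                         noise_sd = config$noise_sd * plateau)
      sh <- if ("coalescence" %in% config$procedures) {
        sample_dose(truth, arrays[[det]], c(0, 5),
                    noise_sd = config$noise_sd * plateau)
      }
      for (proc in config$procedures) {
        map <- if (proc == "SA") iso else {
          tryCatch(coalesce(iso, sh, tolerance = config$coalescence_tolerance),
                   coalescence_error = function(e) NULL)
        }
        if (is.null(map)) {
          n_fail <- n_fail + 1L
          next
        }
        if (plan == 1L) first_plan$maps[[paste(det, proc)]] <- map
        for (ci in seq_along(crits)) {
          series_rows[[length(series_rows) + 1L]] <- data.frame(
            plan = plan, detector = det, procedure = proc,
            criteria = crit_names[ci],
            pass_rate = pass_rate(gamma_map(reference, map, crits[[ci]]))
          )
        }
      }
    }
  }
  series_tab <- do.call(rbind, series_rows)
  say("stage cohort: done (%d coalescence failure(s))", n_fail)

  # ---- stage 3: SPC / PCA --------------------------------------------------
  cohort_of <- function(det, proc, cn) {
    sel <- series_tab$detector == det & series_tab$procedure == proc &
      series_tab$criteria == cn
    qa_series(series_tab$pass_rate[sel][order(series_tab$plan[sel])],
              det, proc, cn)
  }
  spc_rows <- list()
  cap_rows <- list()
  charts <- list()
  for (det in config$detectors) {
    for (cn in crit_names) {
      al_sa <- NULL
      if ("SA" %in% config$procedures) {
        al_sa <- action_limits(cohort_of(det, "SA", cn),
                               beta = config$beta, target = config$target)
      }
      for (proc in config$procedures) {
        s <- cohort_of(det, proc, cn)
        ch <- control_limits(s, baseline_n = min(config$baseline_n, length(s$x)))
        charts[[paste(det, proc, cn, sep = " | ")]] <- ch
        al <- action_limits(s, beta = config$beta, target = config$target)
        fs <- flag_summary(ch)
        spc_rows[[length(spc_rows) + 1L]] <- data.frame(
          detector = det, procedure = proc, criteria = cn,
          n = fs$n, cl = ch$cl, mrbar = ch$mrbar, lcl = ch$lcl,
          n_flagged = fs$n_flagged, percent_flagged = fs$percent,
          delta_a = al$delta_a, lal = al$lal
        )
        if (proc == "coalescence" && !is.null(al_sa)) {
          clean <- remove_out_of_control(s, ch)
          cap <- tryCatch(cpk(clean, lal = al_sa$lal, ual = config$target),
                          error = function(e) NULL)
          if (!is.null(cap)) {
            cap_rows[[length(cap_rows) + 1L]] <- data.frame(
              detector = det, criteria = cn, lal_sa = al_sa$lal,
              cpk = cap$cpk, cpl = cap$cpl, cpu = cap$cpu, p_x = cap$p_x,
              s = cap$s, n_used = length(clean$x)
            )
          }
        }
      }
    }
  }
  spc_tab <- do.call(rbind, spc_rows)
  cap_tab <- if (length(cap_rows)) do.call(rbind, cap_rows)
  comparisons <- list()
  if (all(c("SA", "coalescence") %in% config$procedures)) {
    for (det in config$detectors) {
      for (cn in crit_names) {
        key <- paste(det, cn, sep = " | ")
        comparisons[[key]] <- compare_cohorts(cohort_of(det, "SA", cn),
                                              cohort_of(det, "coalescence", cn))
      }
    }
  }
  say("stage spc: %d cohorts charted", length(charts))

  # ---- stage 4: sensitivity / ROC ------------------------------------------
  sens <- run_error_study(
    n_plans = config$n_error_plans, errors = config$errors,
    detectors = config$detectors, procedures = config$procedures,
    seed = stage_seed(config$seed, "sensitivity"),
    noise_sd = config$noise_sd,
    coalescence_tolerance = config$coalescence_tolerance
  )
  say("stage sensitivity: %d records, %d coalescence failure(s)",
      nrow(sens$records), sens$n_coalescence_failures)

  # ---- stage 5: reconstruction demo + profiles -----------------------------
  set.seed(stage_seed(config$seed, "reconstruction"))
  recon <- NULL
  if (!is.null(first_plan) && length(first_plan$maps)) {
    phantom <- make_phantom("homogeneous_water", lateral = 140, thickness = 200,
                            spacing = 5, det_depth = 97.5)
    beam <- make_beam_model()
    # densely sampled reference reconstruction (full 5 mm lattice)
    gx <- seq(-130, 130, by = 5)
    dense <- measured_map(rep(gx, times = length(gx)), rep(gx, each = length(gx)),
                          interp_grid(first_plan$truth,
                                      rep(gx, times = length(gx)),
                                      rep(gx, each = length(gx))))
    mask <- array(FALSE, dim = dim(phantom$density))
    ctr <- function(ax) abs(ax) <= 50
    mask[ctr(phantom$x), ctr(phantom$y), phantom$z >= 50 & phantom$z <= 150] <- TRUE
    ref_vol <- reconstruct_volume(dense, phantom, beam)
    ref_d50 <- compute_dvh(ref_vol, mask)$d50
    rec_rows <- lapply(names(first_plan$maps), function(nm) {
      vol <- reconstruct_volume(first_plan$maps[[nm]], phantom, beam)
      dv <- compute_dvh(vol, mask, reference = ref_d50)
      data.frame(cohort = nm, d50 = dv$d50, ref_d50 = ref_d50,
                 d50_percent_diff = dv$d50_percent_diff,
                 coverage = vol$coverage$fraction_covered)
    })
    recon <- do.call(rbind, rec_rows)
    say("stage reconstruction: %d cohorts, reference D50 %.3f", nrow(recon), ref_d50)
  }
  profiles <- list()
  if (!is.null(first_plan) && length(first_plan$maps)) {
    for (nm in names(first_plan$maps)) {
      profiles[[nm]] <- profile_compare(
        first_plan$maps[[nm]], first_plan$reference,
        line = list(direction = "lateral", offset = 0)
      )
    }
  }

  structure(
    list(config = config, series = series_tab, spc = spc_tab,
         capability = cap_tab, comparisons = comparisons, charts = charts,
         sensitivity = sens, reconstruction = recon, profiles = profiles,
         n_coalescence_failures = n_fail),
    class = "qa_study"
  )
}

#' @export
print.qa_study <- function(x, ...) {
  cat(sprintf("<qa_study> %d plans, %d gamma series, %d ROC scenarios\n",
              x$config$n_plans, nrow(x$spc), length(x$sensitivity$roc)))
  invisible(x)
}

#' Write the machine-readable study summary
#'
#' Serialises the study's tables (config, pass-rate series, SPC/capability
#' tables, comparisons, sensitivity records, ROC curves, reconstruction and
#' profile summaries) as JSON; every figure is regenerable from this file.
#' Output is byte-identical for identical config and seed.
#'
#' @param study a [run_study()] result.
#' @param path output JSON path.
#' @export
write_study_summary <- function(study, path) {
  cfg <- unclass(study$config)
  cfg$errors <- lapply(cfg$errors, unclass)
  cfg$coalescence_tolerance <-
    if (is.finite(cfg$coalescence_tolerance)) cfg$coalescence_tolerance else "Inf"
  out <- list(
    config = cfg,
    series = study$series,
    spc = study$spc,
    capability = study$capability,
    comparisons = lapply(study$comparisons, function(cc) {
      list(test = cc$test, p_value = cc$p_value, significant = cc$significant,
           summary = cc$summary)
    }),
    sensitivity = list(
      records = study$sensitivity$records,
      n_coalescence_failures = study$sensitivity$n_coalescence_failures,
      roc = lapply(study$sensitivity$roc, function(r) {
        list(auc = r$auc, p_value = r$p_value, fpr = r$curve$fpr,
             tpr = r$curve$tpr)
      })
    ),
    reconstruction = study$reconstruction,
    profiles = study$profiles,
    n_coalescence_failures = study$n_coalescence_failures
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
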