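# End-to-end orchestration: per-API dose translation and the formulation
# analytics report.

#' Run the full oral-to-inhaled dose-translation workflow
#'
#' For each API: build the study-population physiology, rescale Kp to Vdss,
#' simulate the oral validation dose, run NCA, validate against the observed
#' clinical metrics (Cmax and AUC0-inf at the default +/- 20% gate), compute
#' the lung exposure, translate the clinical oral therapeutic dose into an
#' inhaled dose at the fixed FPF (both model-based and tenth-rule), and form
#' the pairwise molar ratios and 25-mg capsule compositions for the two
#' rifampicin-anchored pairs.
#'
#' @param apis APIs to process (default RIF, ETH, MOX; pairs are formed
#'   against the first entry).
#' @param oral_therapeutic_mg Named therapeutic oral doses used for the dose
#'   translation (defaults RIF 600, ETH 1200, MOX 400 mg).
#' @param fpf_percent Fine particle fraction assumed for inhalation
#'   (default 40).
#' @param capsule_fill_mg Capsule fill mass (default 25).
#' @param lung_exposure_percent Optional named vector of lung exposures to
#'   use instead of the simulated ones (e.g. previously reported values);
#'   default `NULL` computes them from the PBPK simulation.
#' @param horizon_h,dt_h Simulation horizon and output step.
#' @param threshold_percent Validation gate (default 20).
#' @param output_dir Optional directory; when given, per-API profile CSVs,
#'   the validation report and the dose-plan table are written there.
#' @return Object of class `dose_translation_report`: `validation`
#'   (a `validation_report`), `exposures`, `dose_plans` (data frame with
#'   model and literature columns), `molar_ratios`, `capsules`, `profiles`.
#' @export
run_dose_translation <- function(apis = c("RIF", "ETH", "MOX"),
                                 oral_therapeutic_mg = c(RIF = 600, ETH = 1200,
                                                         MOX = 400),
                                 fpf_percent = 40, capsule_fill_mg = 25,
                                 lung_exposure_percent = NULL,
                                 horizon_h = 72, dt_h = 0.05,
                                 threshold_percent = 20,
                                 output_dir = NULL) {
  stopifnot(fpf_percent > 0, fpf_percent <= 100)
  sim <- simulated_pk_table(apis, horizon_h = horizon_h, dt_h = dt_h)
  obs <- observed_pk()
  gate_metrics <- c("cmax", "auc_0_inf")
  validation <- validate_model(
    obs[obs$api %in% apis & obs$metric %in% gate_metrics, ],
    sim$metrics[sim$metrics$metric %in% gate_metrics, ],
    threshold_percent = threshold_percent)

  exposures <- numeric(0)
  plans <- list()
  for (api in apis) {
    phys <- build_physiology(study_subject(api))
    expo <- if (!is.null(lung_exposure_percent)) {
      lung_exposure_percent[[api]]
    } else {
      lung_exposure(sim$profiles[[api]], phys)
    }
    exposures[[api]] <- expo
    oral <- oral_therapeutic_mg[[api]]
    model_plan <- inhaled_dose(oral, expo, fpf_percent, source = "model")
    lit_plan <- inhaled_dose(oral, source = "literature-tenth-rule")
    plans[[api]] <- data.frame(
      api = api, oral_dose_mg = oral, lung_exposure_percent = expo,
      fpf_percent = fpf_percent,
      inhaled_dose_model_mg = model_plan$inhaled_dose_mg,
      inhaled_dose_literature_mg = lit_plan$inhaled_dose_mg,
      stringsAsFactors = FALSE)
  }
  dose_plans <- do.call(rbind, c(plans, list(make.row.names = FALSE)))

  anchor <- apis[1]
  mw <- function(api) compound_params(api)$mw_salt
  ratios <- list()
  capsules <- list()
  for (api in setdiff(apis, anchor)) {
    row_a <- dose_plans[dose_plans$api == anchor, ]
    row_b <- dose_plans[dose_plans$api == api, ]
    for (src in c("model", "literature")) {
      col <- paste0("inhaled_dose_", src, "_mg")
      r <- molar_ratio(row_a[[col]], mw(anchor), row_b[[col]], mw(api),
                       api_a = anchor, api_b = api)
      key <- paste(anchor, api, src, sep = "-")
      ratios[[key]] <- r
      capsules[[key]] <- capsule_composition(capsule_fill_mg,
                                             r$ratio_b_per_a,
                                             mw(anchor), mw(api))
    }
  }

  report <- structure(list(validation = validation, exposures = exposures,
                           dose_plans = dose_plans, molar_ratios = ratios,
                           capsules = capsules, profiles = sim$profiles,
                           fpf_percent = fpf_percent),
                      class = "dose_translation_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (api in apis) {
      write_profile_csv(sim$profiles[[api]],
                        file.path(output_dir, paste0("profile_", api, ".csv")))
    }
    write_validation_report(validation,
                            file.path(output_dir, "validation_report.txt"))
    utils::write.csv(dose_plans, file.path(output_dir, "dose_plans.csv"),
                     row.names = FALSE)
    ratio_df <- data.frame(
      pair = names(ratios),
      ratio_b_per_a = vapply(ratios, function(r) r$ratio_b_per_a, numeric(1)),
      quoted = vapply(ratios, format, character(1)))
    utils::write.csv(ratio_df, file.path(output_dir, "molar_ratios.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.dose_translation_report <- function(x, ...) {
  print(x$validation)
  cat("\nLung exposures (%):\n")
  print(round(x$exposures, 3))
  cat("\nDose plans (FPF", x$fpf_percent, "%):\n")
  df <- x$dose_plans
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat("\nMolar ratios:\n")
  for (key in names(x$molar_ratios)) {
    cat(" ", key, ":", format(x$molar_ratios[[key]]), "\n")
  }
  invisible(x)
}

#' Read an impactor run from CSV
#'
#' Expects columns `stage` (values `inhaler_capsule`, `induction_port`,
#' `preseparator`, `filter`) and `mass_ug`; an optional `api` column labels
#' the run.
#'
#' @param path CSV path.
#' @return An [impactor_run()].
#' @export
read_impactor_csv <- function(path) {
  df <- read_checked_csv(path, c("stage", "mass_ug"))
  need <- c("inhaler_capsule", "induction_port", "preseparator", "filter")
  missing <- setdiff(need, df$stage)
  if (length(missing)) {
    stop("impactor CSV ", path, " is missing stage(s): ",
         paste(missing, collapse = ", "))
  }
  m <- stats::setNames(df$mass_ug, df$stage)
  impactor_run(m[["inhaler_capsule"]], m[["induction_port"]],
               m[["preseparator"]], m[["filter"]],
               api = if ("api" %in% names(df)) df$api[1] else "")
}

#' Read a binned particle-size distribution from CSV
#'
#' Expects columns `bin_lo_um`, `bin_hi_um`, `fraction` with contiguous
#' bins.
#'
#' @param path CSV path.
#' @return A [psd_summary()].
#' @export
read_psd_csv <- function(path) {
  df <- read_checked_csv(path, c("bin_lo_um", "bin_hi_um", "fraction"))
  if (any(abs(utils::head(df$bin_hi_um, -1) - utils::tail(df$bin_lo_um, -1)) >
          1e-9)) {
    stop("PSD CSV ", path, " has non-contiguous bins")
  }
  psd_summary(c(df$bin_lo_um[1], df$bin_hi_um), df$fraction)
}

#' Read a dissolution run from CSV
#'
#' Expects columns `time_min`, `conc_ug_per_mL` plus scalar columns
#' `dose_ug`, `vessel_volume_mL`, `sample_volume_mL` (constant per file).
#'
#' @param path CSV path.
#' @return A [dissolution_run()].
#' @export
read_dissolution_csv <- function(path) {
  df <- read_checked_csv(path, c("time_min", "conc_ug_per_mL", "dose_ug",
                                 "vessel_volume_mL", "sample_volume_mL"))
  dissolution_run(times_min = df$time_min,
                  sampled_conc_ug_per_mL = df$conc_ug_per_mL,
                  dose_ug = df$dose_ug[1],
                  vessel_volume_mL = df$vessel_volume_mL[1],
                  sample_volume_mL = df$sample_volume_mL[1])
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty table in ", path)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Formulation analytics report
#'
#' Computes aerodynamic metrics, particle-size summaries and corrected
#' dissolution profiles from CSV inputs (one file per API or formulation),
#' shaped like the tabulated powder-characterisation summaries.
#'
#' @param impactor_csvs Named character vector of impactor CSV paths.
#' @param psd_csvs Named character vector of PSD CSV paths (optional).
#' @param dissolution_csvs Named character vector of dissolution CSV paths
#'   (optional).
#' @return List with `aerosol` (data frame: one row per input, columns
#'   EF%, FPM mg, FPF%), `psd` (data frame of size metrics), `dissolution`
#'   (named list of corrected profiles).
#' @export
run_formulation_report <- function(impactor_csvs = character(0),
                                   psd_csvs = character(0),
                                   dissolution_csvs = character(0)) {
  label_of <- function(paths, i) {
    if (!is.null(names(paths)) && nzchar(names(paths)[i])) names(paths)[i]
    else basename(paths[i])
  }
  aerosol <- NULL
  if (length(impactor_csvs)) {
    rows <- lapply(seq_along(impactor_csvs), function(i) {
      m <- aerosol_metrics(read_impactor_csv(impactor_csvs[i]))
      data.frame(label = label_of(impactor_csvs, i),
                 ef_percent = m$ef_percent, fpm_mg = m$fpm_mg,
                 fpf_percent = m$fpf_percent,
                 emitted_dose_mg = m$emitted_dose_mg,
                 recovered_dose_mg = m$recovered_dose_mg,
                 stringsAsFactors = FALSE)
    })
    aerosol <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  psd <- NULL
  if (length(psd_csvs)) {
    rows <- lapply(seq_along(psd_csvs), function(i) {
      s <- read_psd_csv(psd_csvs[i])
      data.frame(label = label_of(psd_csvs, i), x10 = s$x10, x50 = s$x50,
                 x90 = s$x90, span = s$span, smd = s$smd,
                 frac_below_5um = s$frac_below_5um,
                 stringsAsFactors = FALSE)
    })
    psd <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  dissolution <- NULL
  if (length(dissolution_csvs)) {
    dissolution <- lapply(seq_along(dissolution_csvs), function(i) {
      dissolution_profile(read_dissolution_csv(dissolution_csvs[i]))
    })
    names(dissolution) <- vapply(seq_along(dissolution_csvs),
                                 function(i) label_of(dissolution_csvs, i),
                                 character(1))
  }
  list(aerosol = aerosol, psd = psd, dissolution = dissolution)
}
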