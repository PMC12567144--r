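# Compound parameter blocks for the three anti-TB APIs.

#' Compound parameter set for an anti-TB API
#'
#' Returns the full PBPK/dosing parameter block for rifampicin (RIF),
#' ethambutol (ETH, dosed as the dihydrochloride) or moxifloxacin (MOX, dosed
#' as the hydrochloride): the oral dose used for model validation, free-form
#' and dosed-salt molar masses, blood-to-plasma ratio, fraction unbound,
#' steady-state volume of distribution, effective intestinal permeability,
#' systemic and renal plasma clearances, and the tissue-to-plasma partition
#' coefficients (Kp) for the 13 model tissues.
#'
#' Molar-mass convention: `mw_free` is the free base/zwitterion and is used
#' for tissue-concentration mole ratios; `mw_salt` is the dosed form (RIF is
#' dosed as the free form, ETH as the dihydrochloride, MOX as the
#' hydrochloride) and is used for formulation molar ratios and capsule
#' compositions.
#'
#' @param api_name One of `"RIF"`, `"ETH"`, `"MOX"`.
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(api_name) {
  kp <- switch(api_name,
    RIF = c(Lung = 0.14, Adipose = 0.28, Muscle = 0.15, Liver = 0.29,
            Spleen = 0.19, Heart = 0.14, Brain = 0.16, Kidney = 0.24,
            Skin = 0.19, ReproOrg = 0.24, RedMarrow = 0.30,
            YellowMarrow = 0.30, RestOfBody = 5),
    ETH = c(Lung = 7.92, Adipose = 1.22, Muscle = 9.14, Liver = 8.65,
            Spleen = 8.75, Heart = 7.48, Brain = 8.90, Kidney = 8.07,
            Skin = 6.26, ReproOrg = 8.07, RedMarrow = 3.15,
            YellowMarrow = 3.15, RestOfBody = 46),
    MOX = c(Lung = 4.90, Adipose = 0.52, Muscle = 2.00, Liver = 5.69,
            Spleen = 4.01, Heart = 2.88, Brain = 0.64, Kidney = 6.26,
            Skin = 1.74, ReproOrg = 6.33, RedMarrow = 0.75,
            YellowMarrow = 0.75, RestOfBody = 17.55),
    stop("unknown API name '", api_name, "'; expected one of RIF, ETH, MOX")
  )
  p <- switch(api_name,
    RIF = list(dose_mg = 300, mw_free = 822.94, mw_salt = 822.94,
               bp_ratio = 0.67, fu = 0.15, vdss_L_per_kg = 0.42,
               peff_1e4_cm_s = 1.30, cl_iv_L_per_h = 8.307,
               cl_r_L_per_h = 1.50),
    ETH = list(dose_mg = 1974.6, mw_free = 204.31, mw_salt = 277.23,
               bp_ratio = 0.94, fu = 0.75, vdss_L_per_kg = 6.10,
               peff_1e4_cm_s = 0.67, cl_iv_L_per_h = 41.9,
               cl_r_L_per_h = 32.4),
    MOX = list(dose_mg = 200, mw_free = 401.44, mw_salt = 437.90,
               bp_ratio = 1.14, fu = 0.52, vdss_L_per_kg = 1.90,
               peff_1e4_cm_s = 1.45, cl_iv_L_per_h = 13.15,
               cl_r_L_per_h = 2.54)
  )
  new_compound_params(c(list(name = api_name), p, list(kp = kp)))
}

# internal constructor + invariant checks
new_compound_params <- function(x) {
  obj <- structure(x, class = "compound_params")
  validate_compound_params(obj)
  obj
}

validate_compound_params <- function(params) {
  stopifnot(params$fu > 0, params$fu <= 1,
            params$cl_r_L_per_h <= params$cl_iv_L_per_h,
            all(params$kp > 0),
            params$mw_salt >= params$mw_free,
            params$dose_mg >= 0, params$bp_ratio > 0,
            params$vdss_L_per_kg > 0)
  missing <- setdiff(pbpk_tissues(), names(params$kp))
  if (length(missing)) {
    stop("compound Kp set is missing tissue(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(params$kp), pbpk_tissues())
  if (length(extra)) {
    stop("compound Kp set has unknown tissue(s): ",
         paste(extra, collapse = ", "))
  }
  invisible(params)
}

#' Read a compound parameter file
#'
#' Reads one API's parameter block from a two-column CSV (`parameter`,
#' `value`) whose rows mirror the field names of [compound_params()]; Kp
#' entries are rows named `kp_<Tissue>`. Packaged copies for the three APIs
#' live under `system.file("extdata", package = "lungdose")`.
#'
#' @param path Path to a CSV file.
#' @return A `compound_params` object.
#' @export
read_compound_params <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parameter", "value") %in% names(raw)))
  val <- stats::setNames(raw$value, raw$parameter)
  is_kp <- grepl("^kp_", names(val))
  kp <- as.numeric(val[is_kp])
  names(kp) <- sub("^kp_", "", names(val)[is_kp])
  num <- function(key) as.numeric(val[[key]])
  new_compound_params(list(
    name = val[["name"]],
    dose_mg = num("dose_mg"), mw_free = num("mw_free"),
    mw_salt = num("mw_salt"), bp_ratio = num("bp_ratio"), fu = num("fu"),
    vdss_L_per_kg = num("vdss_L_per_kg"),
    peff_1e4_cm_s = num("peff_1e4_cm_s"),
    cl_iv_L_per_h = num("cl_iv_L_per_h"), cl_r_L_per_h = num("cl_r_L_per_h"),
    kp = kp[pbpk_tissues()]
  ))
}

#' Write a compound parameter file
#'
#' Inverse of [read_compound_params()].
#'
#' @param params A `compound_params` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_params <- function(params, path) {
  validate_compound_params(params)
  scal <- c(name = params$name, dose_mg = params$dose_mg,
            mw_free = params$mw_free, mw_salt = params$mw_salt,
            bp_ratio = params$bp_ratio, fu = params$fu,
            vdss_L_per_kg = params$vdss_L_per_kg,
            peff_1e4_cm_s = params$peff_1e4_cm_s,
            cl_iv_L_per_h = params$cl_iv_L_per_h,
            cl_r_L_per_h = params$cl_r_L_per_h)
  kp <- stats::setNames(params$kp, paste0("kp_", names(params$kp)))
  df <- data.frame(parameter = c(names(scal), names(kp)),
                   value = c(unname(scal), unname(kp)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.compound_params <- function(x, ...) {
  cat("Compound:", x$name,
      sprintf("(dose %.6g mg, MW free %.6g / dosed form %.6g g/mol)\n",
              x$dose_mg, x$mw_free, x$mw_salt))
  cat(sprintf("  bp %.3g, fu %.3g, Vdss %.3g L/kg, Peff %.3g x1e-4 cm/s\n",
              x$bp_ratio, x$fu, x$vdss_L_per_kg, x$peff_1e4_cm_s))
  cat(sprintf("  CLiv %.4g L/h (renal %.4g L/h)\n",
              x$cl_iv_L_per_h, x$cl_r_L_per_h))
  cat("  Kp:", paste(names(x$kp), signif(x$kp, 3), sep = "=",
                     collapse = ", "), "\n")
  invisible(x)
}

#' Observed clinical PK metrics used for validation
#'
#' The observed plasma Cmax (ug/mL), AUC0-t and AUC0-inf (ug*h/mL) from the
#' clinical studies each simulation is validated against, at the oral doses
#' in [compound_params()].
#'
#' @return Data frame with columns `api`, `metric`, `observed`.
#' @export
observed_pk <- function() {
  data.frame(
    api = rep(c("RIF", "ETH", "MOX"), each = 3L),
    metric = rep(c("cmax", "auc_0_t", "auc_0_inf"), times = 3L),
    observed = c(5.81, 31.02, 31.02,
                 3.54, 27.80, 30.76,
                 1.16, 11.88, 14.57),
    stringsAsFactors = FALSE
  )
}
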