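# Dose translation: lung exposure -> inhaled dose at fixed FPF -> salt-aware
# API:API molar ratios -> capsule composition; plus the independent
# tissue-concentration ratio check.

#' Lung exposure percentage from a simulated profile
#'
#' The pulmonary targeting surrogate: the area under the lung-tissue
#' concentration-time curve (extrapolated to infinity by NCA) multiplied by
#' the lung tissue volume in mL, divided by the administered dose in ug, as
#' a percentage:
#' `exposure % = AUCinf_lung (ug*h/mL) * V_lung (mL) / dose (ug) * 100`.
#' For a linear perfusion-limited model this equals
#' `Kp_lung * AUCinf_plasma * V_lung / dose * 100` and is dose-invariant.
#'
#' @param profile A `concentration_profile` containing a `Lung` tissue
#'   series and a recorded dose in ug.
#' @param phys The matching [build_physiology()] table (provides V_lung).
#' @return Lung exposure in percent.
#' @export
lung_exposure <- function(profile, phys) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(phys, "physiology_table"))
  if (!"Lung" %in% colnames(profile$tissue_ug_per_mL)) {
    stop("profile has no Lung tissue series")
  }
  if (!is.finite(profile$dose_ug) || profile$dose_ug <= 0) {
    stop("profile has no positive dose recorded")
  }
  res <- nca(profile$times_h, profile$tissue_ug_per_mL[, "Lung"])
  if (!is.finite(res$auc_0_inf)) stop("lung AUC0-inf unavailable")
  v_lung_mL <- phys$tissue_volumes[["Lung"]] * 1000
  res$auc_0_inf * v_lung_mL / profile$dose_ug * 100
}

#' Inhaled dose from oral dose, lung exposure and fine particle fraction
#'
#' Model-based translation: `inhaled = oral * lung exposure % / FPF %`.
#' The literature tenth-rule alternative (`inhaled = oral / 10`) is exposed
#' through `source = "literature-tenth-rule"`, in which case the exposure
#' argument is ignored.
#'
#' @param oral_dose_mg Oral therapeutic dose (mg, > 0).
#' @param lung_exposure_percent Lung exposure (%, > 0; ignored for the
#'   tenth rule).
#' @param fpf_percent Fine particle fraction (%, in (0, 100]; default 40).
#' @param source `"model"` or `"literature-tenth-rule"`.
#' @return Object of class `dose_plan` with fields `api` (optional, set by
#'   callers), `oral_dose_mg`, `lung_exposure_percent`, `fpf_percent`,
#'   `inhaled_dose_mg`, `source`.
#' @export
inhaled_dose <- function(oral_dose_mg, lung_exposure_percent = NA_real_,
                         fpf_percent = 40,
                         source = c("model", "literature-tenth-rule")) {
  source <- match.arg(source)
  stopifnot(oral_dose_mg > 0)
  if (source == "model") {
    if (!is.finite(lung_exposure_percent) || lung_exposure_percent <= 0) {
      stop("model-based plan needs a positive lung exposure percentage")
    }
    if (!is.finite(fpf_percent) || fpf_percent <= 0 || fpf_percent > 100) {
      stop("FPF must lie in (0, 100]")
    }
    dose <- oral_dose_mg * lung_exposure_percent / fpf_percent
  } else {
    dose <- oral_dose_mg / 10
    lung_exposure_percent <- NA_real_
    fpf_percent <- NA_real_
  }
  structure(list(oral_dose_mg = oral_dose_mg,
                 lung_exposure_percent = lung_exposure_percent,
                 fpf_percent = fpf_percent,
                 inhaled_dose_mg = dose, source = source),
            class = "dose_plan")
}

#' @export
print.dose_plan <- function(x, ...) {
  cat(sprintf("Dose plan [%s]: oral %.6g mg -> inhaled %.6g mg", x$source,
              x$oral_dose_mg, x$inhaled_dose_mg))
  if (x$source == "model") {
    cat(sprintf(" (lung exposure %.4g%%, FPF %.4g%%)",
                x$lung_exposure_percent, x$fpf_percent))
  }
  cat("\n")
  invisible(x)
}

#' Molar ratio of two API doses
#'
#' `(dose_b / mw_b) / (dose_a / mw_a)`, quoted as `1:r`. For formulation
#' ratios the molar masses of the *dosed forms* must be used (RIF free form
#' 822.94 g/mol, ETH dihydrochloride 277.23 g/mol, MOX hydrochloride
#' 437.90 g/mol); see [compound_params()] `mw_salt`.
#'
#' @param dose_a_mg,dose_b_mg Doses of the two APIs (mg of dosed form, > 0).
#' @param mw_a,mw_b Molar masses of the dosed forms (g/mol, > 0).
#' @param api_a,api_b Optional labels.
#' @return Object of class `molar_ratio` with `ratio_b_per_a` and a
#'   `format()`/`print()` rendering as `1:r`.
#' @export
molar_ratio <- function(dose_a_mg, mw_a, dose_b_mg, mw_b,
                        api_a = "A", api_b = "B") {
  stopifnot(dose_a_mg > 0, mw_a > 0, dose_b_mg > 0, mw_b > 0)
  structure(list(api_a = api_a, api_b = api_b,
                 dose_a_mg = dose_a_mg, dose_b_mg = dose_b_mg,
                 mw_a = mw_a, mw_b = mw_b,
                 ratio_b_per_a = (dose_b_mg / mw_b) / (dose_a_mg / mw_a)),
            class = "molar_ratio")
}

#' @export
format.molar_ratio <- function(x, digits = 3, ...) {
  sprintf("1:%s", format(signif(x$ratio_b_per_a, digits)))
}

#' @export
print.molar_ratio <- function(x, ...) {
  cat(sprintf("%s-%s molar ratio %s (%.6g mg / %.6g g/mol vs %.6g mg / %.6g g/mol)\n",
              x$api_a, x$api_b, format(x), x$dose_a_mg, x$mw_a,
              x$dose_b_mg, x$mw_b))
  invisible(x)
}

#' Mole ratio of dose-normalised tissue concentrations
#'
#' Independent check of the modelled molar ratio from published human lung
#' tissue concentrations: each concentration (per 100 mg of oral dose) is
#' converted to moles with the *free-form* molar mass and ratioed:
#' `(c_b / mw_b) / (c_a / mw_a)`.
#'
#' @param conc_a_per_100mg,conc_b_per_100mg Dose-normalised tissue
#'   concentrations (e.g. ug/g per 100 mg oral dose, > 0).
#' @param mw_a,mw_b Free-form molar masses (g/mol, > 0).
#' @return Dimensionless mole ratio b:a.
#' @export
tissue_ratio_check <- function(conc_a_per_100mg, mw_a,
                               conc_b_per_100mg, mw_b) {
  stopifnot(conc_a_per_100mg > 0, mw_a > 0, conc_b_per_100mg > 0, mw_b > 0)
  (conc_b_per_100mg / mw_b) / (conc_a_per_100mg / mw_a)
}

#' Capsule composition for a two-API formulation at a given mole ratio
#'
#' Splits a capsule fill mass between API A and API B so that their mole
#' ratio is `1:ratio_b_per_a` using dosed-form molar masses:
#' `mass_a = fill * mw_a / (mw_a + r * mw_b)`, `mass_b = fill - mass_a`.
#'
#' @param fill_mass_mg Capsule fill mass (mg, default 25).
#' @param ratio_b_per_a Mole ratio of B per mole of A (>= 0).
#' @param mw_a,mw_b Dosed-form molar masses (g/mol, > 0).
#' @return Object of class `capsule_composition` with `mass_a_mg`,
#'   `mass_b_mg`, `fill_mass_mg`, `ratio_b_per_a`.
#' @export
capsule_composition <- function(fill_mass_mg = 25, ratio_b_per_a, mw_a, mw_b) {
  stopifnot(fill_mass_mg > 0, ratio_b_per_a >= 0, mw_a > 0, mw_b > 0)
  mass_a <- fill_mass_mg * mw_a / (mw_a + ratio_b_per_a * mw_b)
  structure(list(fill_mass_mg = fill_mass_mg,
                 ratio_b_per_a = ratio_b_per_a,
                 mass_a_mg = mass_a,
                 mass_b_mg = fill_mass_mg - mass_a),
            class = "capsule_composition")
}

#' @export
print.capsule_composition <- function(x, ...) {
  cat(sprintf("Capsule %.4g mg at 1:%.4g -> A %.3g mg + B %.3g mg\n",
              x$fill_mass_mg, x$ratio_b_per_a, x$mass_a_mg, x$mass_b_mg))
  invisible(x)
}
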