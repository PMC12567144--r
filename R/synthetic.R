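# Synthetic-data generators: every input the analysis stages consume, with
# known ground truth, so the pipeline is testable without instruments.

#' Closed-form oral concentration profiles
#'
#' One-compartment: Bateman function
#' `C(t) = F D ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t))`.
#' Two-compartment oral: bi-exponential disposition with first-order input,
#' computed from `V1`, `V2`, `CL`, `Q`.
#'
#' @param times_h Time grid (h).
#' @param model `"one-compartment-oral"` or `"two-compartment-oral"`.
#' @param dose Dose (mass units set the concentration units).
#' @param f Bioavailable fraction (default 1).
#' @param ka Absorption rate (1/h).
#' @param cl Clearance (L/h).
#' @param v Central volume (L; `V` for one-compartment, `V1` otherwise).
#' @param v2,q Peripheral volume (L) and inter-compartmental clearance
#'   (L/h); two-compartment only.
#' @return Concentrations on `times_h`.
#' @export
oral_model_conc <- function(times_h, model = c("one-compartment-oral",
                                               "two-compartment-oral"),
                            dose, ka, cl, v, f = 1, v2 = NULL, q = NULL) {
  model <- match.arg(model)
  stopifnot(dose >= 0, ka > 0, cl > 0, v > 0, f > 0, f <= 1)
  if (model == "one-compartment-oral") {
    ke <- cl / v
    if (abs(ka - ke) < 1e-12) {
      return(f * dose / v * ka * times_h * exp(-ka * times_h))
    }
    f * dose * ka / (v * (ka - ke)) * (exp(-ke * times_h) - exp(-ka * times_h))
  } else {
    stopifnot(!is.null(v2), !is.null(q), v2 > 0, q > 0)
    k10 <- cl / v; k12 <- q / v; k21 <- q / v2
    s <- k10 + k12 + k21
    alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
    beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
    coef <- function(lam) {
      (k21 - lam) / prod((c(alpha, beta, ka)[c(alpha, beta, ka) != lam] - lam))
    }
    a <- (k21 - alpha) / ((beta - alpha) * (ka - alpha))
    b <- (k21 - beta) / ((alpha - beta) * (ka - beta))
    g <- (k21 - ka) / ((alpha - ka) * (beta - ka))
    f * dose * ka / v *
      (a * exp(-alpha * times_h) + b * exp(-beta * times_h) +
         g * exp(-ka * times_h))
  }
}

#' Generate a noisy observed-style PK profile
#'
#' Evaluates the chosen closed-form oral model on the sampling grid and
#' multiplies each concentration by independent lognormal noise with the
#' requested coefficient of variation (proportional assay error). The
#' ground-truth parameters and noiseless curve are returned alongside.
#'
#' @param times_h Sampling grid (h).
#' @param dose Dose.
#' @param ka,cl,v,f,v2,q Model parameters (see [oral_model_conc()]).
#' @param model Model name.
#' @param cv_percent Proportional noise CV in percent (>= 0, default 15).
#' @param seed Integer seed; required for reproducibility.
#' @return List with `data` (data frame `time_h`, `conc`), `truth` (the
#'   parameters, the noiseless curve, and the analytic `auc_inf = f*dose/cl`).
#' @export
generate_pk_profile <- function(times_h, dose, ka, cl, v, f = 1,
                                model = "one-compartment-oral",
                                v2 = NULL, q = NULL,
                                cv_percent = 15, seed) {
  stopifnot(cv_percent >= 0)
  clean <- oral_model_conc(times_h, model, dose = dose, ka = ka, cl = cl,
                           v = v, f = f, v2 = v2, q = q)
  conc <- if (cv_percent > 0) {
    sdlog <- sqrt(log(1 + (cv_percent / 100)^2))
    clean * withr_seed(seed, stats::rlnorm(length(clean),
                                           meanlog = -sdlog^2 / 2,
                                           sdlog = sdlog))
  } else clean
  list(data = data.frame(time_h = times_h, conc = conc),
       truth = list(model = model, dose = dose, ka = ka, cl = cl, v = v,
                    f = f, v2 = v2, q = q, cv_percent = cv_percent,
                    seed = seed, clean_conc = clean,
                    auc_inf = f * dose / cl))
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate an impactor run with known EF/FPF ground truth
#'
#' Inverts the aerodynamic metric definitions: for targets EF and FPF (in
#' percent) at a given recovered dose, the stage masses are
#' `inhaler = (1 - EF/100) * recovered` (so emitted = impactor mass),
#' `filter = FPF/100 * emitted`, and the remainder is split between the
#' induction port and preseparator. Optional truncated-Gaussian noise is
#' then added per stage; on noiseless output [aerosol_metrics()] returns the
#' targets exactly.
#'
#' @param ef_percent,fpf_percent Targets in `[0, 100]`.
#' @param recovered_dose_ug Total recovered mass (> 0).
#' @param noise_sd_ug Additive Gaussian SD per stage, truncated at zero
#'   (default 0).
#' @param induction_fraction Fraction of the non-filter impactor mass
#'   assigned to the induction port (default 0.5).
#' @param seed Integer seed (required when `noise_sd_ug > 0`).
#' @param api Optional label.
#' @return An [impactor_run()]; ground truth in attribute `truth`.
#' @export
generate_impactor_run <- function(ef_percent, fpf_percent, recovered_dose_ug,
                                  noise_sd_ug = 0, induction_fraction = 0.5,
                                  seed = NULL, api = "") {
  stopifnot(ef_percent >= 0, ef_percent <= 100,
            fpf_percent >= 0, fpf_percent <= 100,
            recovered_dose_ug > 0, noise_sd_ug >= 0)
  if (ef_percent == 0 && fpf_percent > 0) {
    stop("infeasible targets: zero emitted fraction with positive FPF")
  }
  inhaler <- (1 - ef_percent / 100) * recovered_dose_ug
  emitted <- recovered_dose_ug - inhaler
  filt <- fpf_percent / 100 * emitted
  rest <- emitted - filt
  masses <- c(inhaler, rest * induction_fraction,
              rest * (1 - induction_fraction), filt)
  if (noise_sd_ug > 0) {
    if (is.null(seed)) stop("seed required for noisy generation")
    masses <- withr_seed(seed,
      pmax(0, masses + stats::rnorm(4, sd = noise_sd_ug)))
  }
  run <- impactor_run(masses[1], masses[2], masses[3], masses[4], api = api)
  attr(run, "truth") <- list(ef_percent = ef_percent,
                             fpf_percent = fpf_percent,
                             recovered_dose_ug = recovered_dose_ug,
                             noise_sd_ug = noise_sd_ug, seed = seed)
  run
}

#' Generate a dissolution run with exact withdrawal bookkeeping
#'
#' Simulates the small-volume dissolution test on a known true release
#' curve, tracking exactly how much drug each withdrawn-and-replaced aliquot
#' removes from the vessel. The resulting sampled concentrations are the
#' exact oracle for the correction applied by [dissolution_profile()].
#'
#' @param release_fraction Function of time (min) returning the cumulative
#'   fraction of the dose released (monotone, in `[0, 1]`).
#' @param dose_ug Dose on the filter (> 0).
#' @param times_min Sampling grid (default the standard grid).
#' @param vessel_volume_mL,sample_volume_mL Vessel and aliquot volumes.
#' @return A [dissolution_run()]; the true released fractions at the sample
#'   times in attribute `truth`.
#' @export
generate_dissolution_run <- function(release_fraction, dose_ug,
                                     times_min = c(0, 2, 5, 10, 20, 40, 60,
                                                   120, 180),
                                     vessel_volume_mL = 55,
                                     sample_volume_mL = 1) {
  stopifnot(is.function(release_fraction), dose_ug > 0)
  frac <- vapply(times_min, release_fraction, numeric(1))
  if (any(frac < -1e-12) || any(frac > 1 + 1e-12)) {
    stop("release fraction must stay within [0, 1] of the dose")
  }
  if (any(diff(frac) < -1e-12)) stop("release curve must be monotone")
  conc <- numeric(length(times_min))
  removed <- 0  # drug carried away by previous aliquots
  for (i in seq_along(times_min)) {
    in_vessel <- frac[i] * dose_ug - removed
    conc[i] <- in_vessel / vessel_volume_mL
    removed <- removed + conc[i] * sample_volume_mL
  }
  run <- dissolution_run(times_min = times_min,
                         sampled_conc_ug_per_mL = conc, dose_ug = dose_ug,
                         vessel_volume_mL = vessel_volume_mL,
                         sample_volume_mL = sample_volume_mL)
  attr(run, "truth") <- list(release_fraction_at_samples = frac)
  run
}
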