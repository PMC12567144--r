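# Formulation analytics: fast-screening-impactor metrics, content
# uniformity, particle-size summaries, and dissolution with sampling-volume
# correction.

#' Construct a fast-screening impactor run
#'
#' Per-API deposition masses (ug) on the four collection locations of a
#' fast-screening impactor test with a capsule inhaler: drug retained in the
#' inhaler + capsule, the mouthpiece + induction port, the preseparator
#' (coarse fraction, aerodynamic diameter > 5 um), and the fine-fraction
#' collector filter (< 5 um).
#'
#' @param inhaler_capsule_ug,induction_port_ug,preseparator_ug,filter_ug
#'   Stage masses in ug (>= 0, at least one positive).
#' @param flow_L_per_min Air flow (default 60).
#' @param actuation_s Actuation time (default 4).
#' @param fill_mass_mg Nominal capsule fill (default 25).
#' @param api Optional API label.
#' @return Object of class `impactor_run`.
#' @export
impactor_run <- function(inhaler_capsule_ug, induction_port_ug,
                         preseparator_ug, filter_ug,
                         flow_L_per_min = 60, actuation_s = 4,
                         fill_mass_mg = 25, api = "") {
  m <- c(inhaler_capsule = inhaler_capsule_ug,
         induction_port = induction_port_ug,
         preseparator = preseparator_ug, filter = filter_ug)
  stopifnot(all(m >= 0))
  if (sum(m) <= 0) stop("recovered dose must be positive")
  structure(list(stage_masses_ug = m, flow_L_per_min = flow_L_per_min,
                 actuation_s = actuation_s, fill_mass_mg = fill_mass_mg,
                 api = api),
            class = "impactor_run")
}

#' Aerodynamic metrics from an impactor run
#'
#' Emitted dose = recovered dose minus drug left in the inhaler and capsule.
#' The emitted fraction EF is the percentage of the *recovered* dose found in
#' the impactor (induction port + preseparator + filter). The fine particle
#' mass FPM is the filter (< 5 um) mass, and the fine particle fraction FPF
#' is FPM as a percentage of the emitted dose. Variants normalised to the
#' nominal fill mass are reported alongside as `ef_nominal_percent` /
#' `fpf_nominal_percent` but are not the reference definitions.
#'
#' @param run An [impactor_run()].
#' @return Object of class `aerosol_metrics`: `recovered_dose_mg`,
#'   `emitted_dose_mg`, `ef_percent`, `fpm_mg`, `fpf_percent`, plus the
#'   nominal-dose variants.
#' @export
aerosol_metrics <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  m <- run$stage_masses_ug
  recovered <- sum(m)
  emitted <- recovered - m[["inhaler_capsule"]]
  impactor_mass <- m[["induction_port"]] + m[["preseparator"]] + m[["filter"]]
  # guard the [0, 100] invariant against summation round-off
  ef <- min(100, 100 * impactor_mass / recovered)
  fpm <- m[["filter"]]
  if (emitted <= 0) {
    if (fpm > 0) stop("inconsistent run: zero emitted dose but non-zero filter mass")
    warning("zero emitted dose; FPF reported as 0")
    fpf <- 0
  } else {
    fpf <- min(100, 100 * fpm / emitted)
  }
  nominal_ug <- run$fill_mass_mg * 1000
  structure(list(api = run$api,
                 recovered_dose_mg = recovered / 1000,
                 emitted_dose_mg = emitted / 1000,
                 ef_percent = ef,
                 fpm_mg = fpm / 1000,
                 fpf_percent = fpf,
                 ef_nominal_percent = 100 * impactor_mass / nominal_ug,
                 fpf_nominal_percent = 100 * fpm / nominal_ug),
            class = "aerosol_metrics")
}

#' @export
print.aerosol_metrics <- function(x, ...) {
  cat(sprintf("Aerosol metrics%s: EF %.1f%%, FPM %.3g mg, FPF %.1f%% ",
              if (nzchar(x$api)) paste0(" (", x$api, ")") else "",
              x$ef_percent, x$fpm_mg, x$fpf_percent))
  cat(sprintf("(recovered %.3g mg, emitted %.3g mg)\n",
              x$recovered_dose_mg, x$emitted_dose_mg))
  invisible(x)
}

#' Content uniformity and mixing homogeneity
#'
#' Mean assayed drug content with its sample standard deviation and relative
#' standard deviation. Uniformity passes when the mean lies within the
#' acceptance band around 100% of label claim (default +/- 15 points);
#' homogeneity passes when the RSD is below the homogeneity limit
#' (default 5%).
#'
#' @param samples Assayed contents as % of label claim (length >= 2).
#' @param uniformity_band Half-width of the uniformity band (default 15).
#' @param rsd_limit Homogeneity RSD limit (default 5).
#' @return List with `mean`, `sd`, `rsd_percent`, `n`, `uniformity_pass`,
#'   `homogeneity_pass`.
#' @export
content_uniformity <- function(samples, uniformity_band = 15, rsd_limit = 5) {
  if (length(samples) < 2L) stop("need at least 2 assayed samples")
  m <- mean(samples)
  s <- stats::sd(samples)
  rsd <- 100 * s / m
  list(mean = m, sd = s, rsd_percent = rsd, n = length(samples),
       uniformity_pass = m >= 100 - uniformity_band & m <= 100 + uniformity_band,
       homogeneity_pass = rsd < rsd_limit)
}

#' Particle-size distribution summary from binned data
#'
#' Computes the x10/x50/x90 quantiles by linear interpolation of the
#' cumulative volume distribution over the bin edges, the SPAN
#' `(x90 - x10)/x50`, the Sauter mean diameter
#' `SMD = 1 / sum(f_i / d_i)` with geometric-mean bin diameters, and the
#' volume percentage below 5 um.
#'
#' @param bin_edges_um Increasing vector of `n + 1` bin edges (um, > 0).
#' @param volume_fractions `n` volume fractions summing to 1 (within 1e-6).
#' @return Object of class `psd_summary`: `x10`, `x50`, `x90`, `span`,
#'   `smd`, `frac_below_5um`.
#' @export
psd_summary <- function(bin_edges_um, volume_fractions) {
  n <- length(volume_fractions)
  if (length(bin_edges_um) != n + 1L) stop("need n+1 bin edges for n fractions")
  if (any(diff(bin_edges_um) <= 0)) stop("bin edges must be strictly increasing")
  if (any(bin_edges_um <= 0)) stop("bin edges must be positive")
  if (abs(sum(volume_fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  cum <- c(0, cumsum(volume_fractions))
  qfun <- function(p) stats::approx(cum, bin_edges_um, xout = p,
                                    ties = "ordered")$y
  x10 <- qfun(0.10); x50 <- qfun(0.50); x90 <- qfun(0.90)
  d_geo <- sqrt(utils::head(bin_edges_um, -1) * utils::tail(bin_edges_um, -1))
  smd <- 1 / sum(volume_fractions / d_geo)
  below5 <- stats::approx(bin_edges_um, cum, xout = 5, rule = 2,
                          ties = "ordered")$y
  structure(list(x10 = x10, x50 = x50, x90 = x90,
                 span = psd_span(x10, x50, x90), smd = smd,
                 frac_below_5um = 100 * below5),
            class = "psd_summary")
}

#' SPAN of a particle-size distribution
#'
#' `(x90 - x10) / x50` from the three standard quantiles.
#'
#' @param x10,x50,x90 Size quantiles (um); must satisfy `x10 <= x50 <= x90`.
#' @return Dimensionless SPAN.
#' @export
psd_span <- function(x10, x50, x90) {
  stopifnot(x10 <= x50, x50 <= x90, x50 > 0)
  (x90 - x10) / x50
}

#' @export
print.psd_summary <- function(x, ...) {
  cat(sprintf("PSD: x10 %.3g, x50 %.3g, x90 %.3g um; SPAN %.3g; SMD %.3g um; %.1f%% < 5 um\n",
              x$x10, x$x50, x$x90, x$span, x$smd, x$frac_below_5um))
  invisible(x)
}

#' Construct a dissolution run
#'
#' A small-volume dissolution test of the fine-particle filter dose in
#' simulated lung fluid: at each sampling time a fixed aliquot is withdrawn
#' for assay and immediately replaced with fresh medium, so the measured
#' concentrations under-report the cumulative amount released.
#'
#' @param times_min Strictly increasing sampling times (min); default the
#'   standard grid `c(0, 2, 5, 10, 20, 40, 60, 120, 180)`.
#' @param sampled_conc_ug_per_mL Assayed concentrations at those times.
#' @param dose_ug Theoretical API dose on the filter (> 0).
#' @param vessel_volume_mL Medium volume (default 55).
#' @param sample_volume_mL Withdrawn aliquot (default 1; must be smaller
#'   than the vessel volume).
#' @return Object of class `dissolution_run`.
#' @export
dissolution_run <- function(times_min = c(0, 2, 5, 10, 20, 40, 60, 120, 180),
                            sampled_conc_ug_per_mL, dose_ug,
                            vessel_volume_mL = 55, sample_volume_mL = 1) {
  stopifnot(length(sampled_conc_ug_per_mL) == length(times_min),
            all(diff(times_min) > 0), all(sampled_conc_ug_per_mL >= 0),
            sample_volume_mL >= 0, sample_volume_mL < vessel_volume_mL)
  if (dose_ug <= 0) stop("dose on filter must be positive")
  structure(list(times_min = times_min,
                 sampled_conc_ug_per_mL = sampled_conc_ug_per_mL,
                 dose_ug = dose_ug, vessel_volume_mL = vessel_volume_mL,
                 sample_volume_mL = sample_volume_mL),
            class = "dissolution_run")
}

#' Cumulative dissolution profile with sampling-volume correction
#'
#' Reconstructs the cumulative percentage of the dose dissolved, correcting
#' for the drug removed by each withdrawn-and-replaced aliquot: the amount
#' in solution at sample `n` is `C_n * V + v * sum_{i<n} C_i` (vessel volume
#' `V`, aliquot `v`). A decreasing corrected series produces a warning (not
#' an error) since drug degradation in aqueous medium is a real observation.
#'
#' @param run A [dissolution_run()].
#' @return Data frame `time_min`, `conc_ug_per_mL`,
#'   `cumulative_amount_ug`, `percent_dissolved`.
#' @export
dissolution_profile <- function(run) {
  stopifnot(inherits(run, "dissolution_run"))
  conc <- run$sampled_conc_ug_per_mL
  v <- run$sample_volume_mL
  V <- run$vessel_volume_mL
  prior <- c(0, utils::head(cumsum(conc), -1))
  amount <- conc * V + v * prior
  pct <- 100 * amount / run$dose_ug
  if (any(diff(pct) < -1e-9)) {
    warning("corrected dissolution series is not monotone ",
            "(possible degradation)")
  }
  data.frame(time_min = run$times_min, conc_ug_per_mL = conc,
             cumulative_amount_ug = amount, percent_dissolved = pct)
}
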