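# Virtual-subject physiology: tissue volumes and regional blood flows.

#' Tissue names used by the whole-body model
#'
#' The 13 perfused tissue compartments of the whole-body PBPK model, in the
#' order used throughout the package. `RestOfBody` is the residual carcass
#' (bone mineral, gut wall, connective tissue, glands) not covered by a named
#' organ.
#'
#' @return Character vector of 13 tissue names.
#' @export
pbpk_tissues <- function() {
  c("Lung", "Adipose", "Muscle", "Liver", "Spleen", "Heart", "Brain",
    "Kidney", "Skin", "ReproOrg", "RedMarrow", "YellowMarrow", "RestOfBody")
}

#' Reference human physiology
#'
#' A reference adult male of 73 kg used as the scaling anchor for virtual
#' subjects. Tissue volumes (L) are standard reference-man organ sizes; blood
#' flows are expressed as fractions of cardiac output (390 L/h at 73 kg).
#' The lung volume (1.17 L) is the whole-lung tissue mass convention, since
#' the lung-exposure metric multiplies lung AUC by this volume directly.
#' `RestOfBody` volume is total body volume (weight over a body density of
#' 1.05 kg/L) minus all named tissues and blood; its flow is the residual
#' cardiac output not assigned to a named organ. The liver flow fraction is
#' its *arterial-side* inflow (hepatic artery plus splanchnic flow that is not
#' carried by a modelled portal tissue); total liver perfusion is this inflow
#' plus the outflow of the portal tissues (spleen), i.e. 25.5% of cardiac
#' output.
#'
#' @return A data frame with columns `tissue`, `volume_L_per_73kg`,
#'   `flow_fraction_of_co`, plus attributes `co_L_per_h_73kg` (390),
#'   `blood_volume_L_73kg` (5.6), `venous_fraction` (0.7), `hematocrit`
#'   (0.45), `reference_weight_kg` (73) and `portal_tissues` ("Spleen").
#' @export
reference_physiology <- function() {
  vol <- c(Lung = 1.17, Adipose = 18.2, Muscle = 29.0, Liver = 1.80,
           Spleen = 0.19, Heart = 0.33, Brain = 1.45, Kidney = 0.31,
           Skin = 3.30, ReproOrg = 0.035, RedMarrow = 1.17,
           YellowMarrow = 2.48, RestOfBody = NA_real_)
  blood <- 5.6
  # residual carcass closes the volume balance at body density 1.05 kg/L
  vol["RestOfBody"] <- 73 / 1.05 - sum(vol, na.rm = TRUE) - blood
  # arterial-side inflow fractions; lung carries total cardiac output and is
  # marked NA here. Fractions sum to 1 exactly (RestOfBody is the residual).
  flow <- c(Lung = NA_real_, Adipose = 0.05, Muscle = 0.17, Liver = 0.225,
            Spleen = 0.03, Heart = 0.04, Brain = 0.12, Kidney = 0.19,
            Skin = 0.05, ReproOrg = 0.0005, RedMarrow = 0.03,
            YellowMarrow = 0.01, RestOfBody = NA_real_)
  flow["RestOfBody"] <- 1 - sum(flow, na.rm = TRUE)
  ref <- data.frame(tissue = pbpk_tissues(),
                    volume_L_per_73kg = unname(vol[pbpk_tissues()]),
                    flow_fraction_of_co = unname(flow[pbpk_tissues()]),
                    stringsAsFactors = FALSE)
  attr(ref, "co_L_per_h_73kg") <- 390
  attr(ref, "blood_volume_L_73kg") <- blood
  attr(ref, "venous_fraction") <- 0.7
  attr(ref, "hematocrit") <- 0.45
  attr(ref, "reference_weight_kg") <- 73
  attr(ref, "portal_tissues") <- "Spleen"
  ref
}

#' Read a reference-physiology table from CSV
#'
#' Reads the same layout that [reference_physiology()] returns, from a CSV
#' with columns `tissue`, `volume_L_per_73kg`, `flow_fraction_of_co` and
#' scalar rows encoded as `tissue = "<attribute>"` pairs in the companion
#' columns. The packaged copy lives at
#' `system.file("extdata", "reference_physiology.csv", package = "lungdose")`.
#'
#' @param path Path to a CSV file.
#' @return A reference-physiology data frame (see [reference_physiology()]).
#' @export
read_reference_physiology <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  scal <- raw[!(raw$tissue %in% pbpk_tissues()), ]
  tis <- raw[raw$tissue %in% pbpk_tissues(), ]
  ref <- data.frame(tissue = tis$tissue,
                    volume_L_per_73kg = tis$volume_L_per_73kg,
                    flow_fraction_of_co = tis$flow_fraction_of_co,
                    stringsAsFactors = FALSE)
  get_scalar <- function(key) {
    v <- scal$volume_L_per_73kg[scal$tissue == key]
    if (length(v) != 1L) stop("reference physiology file misses scalar '", key, "'")
    v
  }
  attr(ref, "co_L_per_h_73kg") <- get_scalar("co_L_per_h_73kg")
  attr(ref, "blood_volume_L_73kg") <- get_scalar("blood_volume_L_73kg")
  attr(ref, "venous_fraction") <- get_scalar("venous_fraction")
  attr(ref, "hematocrit") <- get_scalar("hematocrit")
  attr(ref, "reference_weight_kg") <- get_scalar("reference_weight_kg")
  attr(ref, "portal_tissues") <- "Spleen"
  ref
}

#' Construct a virtual subject
#'
#' @param body_weight_kg Body weight in kg (> 0).
#' @param body_height_cm Body height in cm (> 0).
#' @param age_years Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param label Free-text label.
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(body_weight_kg, body_height_cm, age_years,
                            sex = c("male", "female"), label = "") {
  sex <- match.arg(sex)
  stopifnot(is.numeric(body_weight_kg), body_weight_kg > 0,
            is.numeric(body_height_cm), body_height_cm > 0,
            is.numeric(age_years), age_years > 0)
  structure(list(body_weight_kg = body_weight_kg,
                 body_height_cm = body_height_cm,
                 age_years = age_years, sex = sex, label = label),
            class = "virtual_subject")
}

#' Mean study-population subject for an API
#'
#' Returns the mean anthropometrics of the clinical study population whose
#' plasma data each compound's simulation is validated against. All three
#' virtual individuals are built as male, matching the single representative
#' male Caucasian profile used per compound.
#'
#' @param api_name One of `"RIF"`, `"ETH"`, `"MOX"`.
#' @return A `virtual_subject`.
#' @export
study_subject <- function(api_name) {
  tab <- list(
    RIF = list(w = 85.5, h = 176.4, a = 30.0),
    ETH = list(w = 79.3, h = 172.6, a = 39.1),
    MOX = list(w = 81.5, h = 182.2, a = 33.6)
  )
  if (!api_name %in% names(tab)) {
    stop("unknown API name '", api_name, "'; expected one of RIF, ETH, MOX")
  }
  p <- tab[[api_name]]
  virtual_subject(p$w, p$h, p$a, sex = "male",
                  label = paste0(api_name, " study population mean"))
}

#' Build subject physiology from a reference human
#'
#' Tissue volumes scale linearly with body weight relative to the reference
#' human; cardiac output scales allometrically with weight^0.75; regional
#' blood flows keep their reference fractions of cardiac output. Height and
#' age are carried along but do not enter the scaling.
#'
#' @param subject A [virtual_subject()].
#' @param reference Reference physiology, default [reference_physiology()].
#' @return An object of class `physiology_table`: list with `tissue_volumes`
#'   (named, L), `blood_flows` (named, L/h; the `Liver` entry is total liver
#'   perfusion), `cardiac_output` (L/h), `hepatic_artery_flow` (L/h, the
#'   liver's arterial-side inflow), `portal_inflow_tissues`, `venous_blood_L`,
#'   `arterial_blood_L`, `plasma_volume_L`, `hematocrit`, `body_weight_kg`.
#' @export
build_physiology <- function(subject, reference = reference_physiology()) {
  stopifnot(inherits(subject, "virtual_subject"))
  missing <- setdiff(pbpk_tissues(), reference$tissue)
  if (length(missing)) {
    stop("reference physiology is missing tissue(s): ",
         paste(missing, collapse = ", "))
  }
  ref_w <- attr(reference, "reference_weight_kg")
  w_scale <- subject$body_weight_kg / ref_w
  co <- attr(reference, "co_L_per_h_73kg") * w_scale^0.75

  vols <- stats::setNames(reference$volume_L_per_73kg, reference$tissue)
  vols <- vols[pbpk_tissues()] * w_scale
  fr <- stats::setNames(reference$flow_fraction_of_co, reference$tissue)
  fr <- fr[pbpk_tissues()]

  flows <- fr * co
  flows["Lung"] <- co
  portal <- attr(reference, "portal_tissues")
  hepatic_artery <- fr[["Liver"]] * co
  # reported liver flow is total perfusion: arterial inflow + portal inflow
  flows["Liver"] <- hepatic_artery + sum(flows[portal])

  blood <- attr(reference, "blood_volume_L_73kg") * w_scale
  ven_frac <- attr(reference, "venous_fraction")
  hct <- attr(reference, "hematocrit")

  phys <- structure(list(
    tissue_volumes = vols,
    blood_flows = flows,
    cardiac_output = co,
    hepatic_artery_flow = hepatic_artery,
    portal_inflow_tissues = portal,
    venous_blood_L = blood * ven_frac,
    arterial_blood_L = blood * (1 - ven_frac),
    plasma_volume_L = blood * (1 - hct),
    hematocrit = hct,
    body_weight_kg = subject$body_weight_kg,
    subject = subject
  ), class = "physiology_table")
  validate_physiology(phys)
  phys
}

# internal: flow-balance and positivity checks, run after every build
validate_physiology <- function(phys) {
  stopifnot(all(phys$tissue_volumes > 0), all(phys$blood_flows > 0),
            phys$cardiac_output > 0)
  # arterial outflows (everything except lung; liver enters via its arterial
  # inflow, the portal tissues carry their own fractions) must return the
  # cardiac output
  arterial_in <- sum(phys$blood_flows[setdiff(pbpk_tissues(), c("Lung", "Liver"))]) +
    phys$hepatic_artery_flow
  if (abs(arterial_in - phys$cardiac_output) > 1e-9 * phys$cardiac_output) {
    stop("physiology flow balance violated: arterial inflows ",
         format(arterial_in), " != cardiac output ",
         format(phys$cardiac_output))
  }
  invisible(phys)
}

#' @export
print.physiology_table <- function(x, ...) {
  cat("Whole-body physiology for", format(x$body_weight_kg), "kg subject\n")
  cat("  cardiac output:", format(round(x$cardiac_output, 1)), "L/h\n")
  cat("  blood volume:",
      format(round(x$venous_blood_L + x$arterial_blood_L, 2)), "L (plasma",
      format(round(x$plasma_volume_L, 2)), "L)\n")
  df <- data.frame(volume_L = round(x$tissue_volumes, 3),
                   flow_L_per_h = round(x$blood_flows, 1))
  print(df, ...)
  invisible(x)
}
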