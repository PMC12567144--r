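# Shared fixtures: small constructed objects used across test files.

# a compound with simple round numbers on the full 13-tissue map
toy_params <- function(kp_value = 1, bp = 1, fu = 0.5, vdss = 1,
                       cl_iv = 10, cl_r = 0, dose_mg = 100) {
  kp <- stats::setNames(rep(kp_value, 13), pbpk_tissues())
  structure(list(name = "TOY", dose_mg = dose_mg, mw_free = 300,
                 mw_salt = 300, bp_ratio = bp, fu = fu,
                 vdss_L_per_kg = vdss, peff_1e4_cm_s = 1,
                 cl_iv_L_per_h = cl_iv, cl_r_L_per_h = cl_r, kp = kp),
            class = "compound_params")
}

ref_subject <- function(weight = 73) {
  virtual_subject(weight, 176, 30, sex = "male", label = "test")
}

# physiology whose perfusion is inflated so every tissue equilibrates almost
# instantly; with uniform Kp = 1 and bp = 1 the whole body then behaves as a
# single well-mixed compartment
fast_physiology <- function(weight = 73, speedup = 2000) {
  ref <- reference_physiology()
  attr(ref, "co_L_per_h_73kg") <- attr(ref, "co_L_per_h_73kg") * speedup
  build_physiology(ref_subject(weight), reference = ref)
}

# volume of the single well-mixed compartment the model collapses to when
# Kp = 1 and bp = 1 everywhere (blood pools plus all tissues)
total_body_volume_L <- function(phys) {
  phys$venous_blood_L + phys$arterial_blood_L + sum(phys$tissue_volumes)
}
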