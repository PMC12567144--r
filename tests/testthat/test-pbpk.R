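test_that("Kp rescaling solves the steady-state volume identity", {
  phys <- build_physiology(study_subject("ETH"))
  params <- rescale_kp_to_vdss(compound_params("ETH"), phys)
  vss <- phys$plasma_volume_L + sum(params$kp * phys$tissue_volumes)
  expect_equal(vss, 6.1 * 79.3, tolerance = 1e-6)
  expect_equal(vss, 483.73, tolerance = 1e-6)

  # a Kp set that already satisfies the identity is left untouched (s = 1)
  satisfied <- params
  satisfied$kp_scale_factor <- NULL
  again <- rescale_kp_to_vdss(satisfied, phys)
  expect_equal(again$kp_scale_factor, 1, tolerance = 1e-12)
  expect_equal(again$kp, params$kp, tolerance = 1e-12)

  # doubling every Kp on input is undone by s = 0.5
  doubled <- satisfied
  doubled$kp <- 2 * satisfied$kp
  undone <- rescale_kp_to_vdss(doubled, phys)
  expect_equal(undone$kp_scale_factor, 0.5, tolerance = 1e-12)
  expect_equal(undone$kp, params$kp, tolerance = 1e-12)
})

test_that("rescaling rejects an unreachable Vdss", {
  phys <- build_physiology(study_subject("RIF"))
  params <- compound_params("RIF")
  params$vdss_L_per_kg <- 0.01  # below the plasma volume alone
  expect_error(rescale_kp_to_vdss(params, phys), "non-positive")
})

test_that("the absorption model follows ka = 2 Peff / r with its limits", {
  # frozen regression value for rifampicin geometry
  abs_rif <- absorption_from_peff(1.3, radius_cm = 1.25,
                                  transit_time_h = 3.32, n_transit = 7)
  expect_equal(abs_rif$ka_per_h, 2 * 1.3e-4 / 1.25 * 3600, tolerance = 1e-12)
  expect_equal(abs_rif$ka_per_h, 0.7488, tolerance = 1e-4)
  expect_equal(abs_rif$fa,
               1 - (1 + 0.7488 * 3.32 / 7)^(-7), tolerance = 1e-4)

  # vanishing permeability absorbs nothing; very fast absorption everything
  expect_lt(fraction_absorbed(1e-8, 3.32, 7), 1e-7)
  expect_gt(fraction_absorbed(1e4, 3.32, 7), 1 - 1e-10)
  expect_error(absorption_from_peff(0))
})

test_that("zero dose yields an identically zero profile", {
  phys <- build_physiology(ref_subject())
  params <- rescale_kp_to_vdss(toy_params(vdss = 0.5), phys)
  prof <- simulate_pbpk(params, phys, absorption_from_peff(1), dose_mg = 0,
                        horizon_h = 24, dt_h = 0.5)
  expect_equal(max(abs(prof$plasma_ug_per_mL)), 0)
  expect_equal(max(abs(prof$tissue_ug_per_mL)), 0)
})

test_that("mass balance closes within 0.1% of dose at every output time", {
  for (api in c("RIF", "ETH", "MOX")) {
    phys <- build_physiology(study_subject(api))
    params <- rescale_kp_to_vdss(compound_params(api), phys)
    prof <- simulate_pbpk(params, phys,
                          absorption_from_peff(params$peff_1e4_cm_s),
                          horizon_h = 48, dt_h = 0.25)
    bal <- prof$amounts_balance
    total <- bal$gut_ug + bal$body_ug + bal$eliminated_ug + bal$transit_lost_ug
    expect_lt(max(abs(total - prof$dose_ug)) / prof$dose_ug, 1e-3,
              label = paste(api, "mass balance"))
  }
})

test_that("the model is linear in dose", {
  phys <- build_physiology(study_subject("MOX"))
  params <- rescale_kp_to_vdss(compound_params("MOX"), phys)
  absorption <- absorption_from_peff(params$peff_1e4_cm_s)
  p1 <- simulate_pbpk(params, phys, absorption, dose_mg = 200,
                      horizon_h = 48, dt_h = 0.25)
  p2 <- simulate_pbpk(params, phys, absorption, dose_mg = 400,
                      horizon_h = 48, dt_h = 0.25)
  scale <- p2$plasma_ug_per_mL[-1] / p1$plasma_ug_per_mL[-1]
  expect_equal(scale, rep(2, length(scale)), tolerance = 1e-6)
})

test_that("plasma AUC0-inf equals Fa*Fh*Dose/CL for all three APIs", {
  for (api in c("RIF", "ETH", "MOX")) {
    phys <- build_physiology(study_subject(api))
    params <- rescale_kp_to_vdss(compound_params(api), phys)
    absorption <- absorption_from_peff(params$peff_1e4_cm_s)
    prof <- simulate_pbpk(params, phys, absorption)
    res <- nca(prof$times_h, prof$plasma_ug_per_mL)
    f_sys <- prof$fa_predicted * (1 - prof$hepatic_extraction)
    analytic <- f_sys * params$dose_mg / params$cl_iv_L_per_h
    expect_equal(res$auc_0_inf, analytic, tolerance = 0.01,
                 label = paste(api, "AUC identity"))
  }
})

test_that("tissue-to-plasma AUC ratios recover every rescaled Kp", {
  for (api in c("RIF", "ETH", "MOX")) {
    phys <- build_physiology(study_subject(api))
    params <- rescale_kp_to_vdss(compound_params(api), phys)
    absorption <- absorption_from_peff(params$peff_1e4_cm_s)
    prof <- simulate_pbpk(params, phys, absorption, horizon_h = 96)
    auc_plasma <- nca(prof$times_h, prof$plasma_ug_per_mL)$auc_0_inf
    for (tissue in setdiff(pbpk_tissues(), c("Liver", "Kidney"))) {
      auc_tis <- nca(prof$times_h, prof$tissue_ug_per_mL[, tissue])$auc_0_inf
      expect_equal(auc_tis / auc_plasma, unname(params$kp[tissue]),
                   tolerance = 0.01,
                   label = paste(api, tissue, "AUC ratio"))
    }
  }
})

test_that("with uniform Kp, unit bp and fast perfusion the model collapses
           to the one-compartment oral closed form", {
  phys <- fast_physiology()
  v_eff <- total_body_volume_L(phys)
  ke <- 0.2
  params <- toy_params(kp_value = 1, bp = 1, cl_iv = ke * v_eff, cl_r = 0,
                       dose_mg = 100, vdss = 1)
  params$kp_scale_factor <- 1  # bypass rescaling: Kp must stay exactly 1
  absorption <- structure(list(ka_per_h = 1, n_transit = 1L,
                               transit_time_h = 1e8,
                               fa = 1), class = "absorption_model")
  prof <- simulate_pbpk(params, phys, absorption, horizon_h = 48, dt_h = 0.05)
  # mg and L give mg/L = ug/mL directly
  bateman <- oral_model_conc(prof$times_h, "one-compartment-oral",
                             dose = 100, ka = 1, cl = ke * v_eff, v = v_eff)
  expect_lt(max(abs(prof$plasma_ug_per_mL - bateman)) / max(bateman), 0.005)
})

test_that("with no elimination the body retains the absorbed dose and
           tissues equilibrate to their Kp", {
  phys <- build_physiology(ref_subject())
  params <- toy_params(kp_value = 2, bp = 1, cl_iv = 0, cl_r = 0,
                       dose_mg = 50)
  params$kp_scale_factor <- 1
  absorption <- absorption_from_peff(2)
  prof <- simulate_pbpk(params, phys, absorption, horizon_h = 400,
                        dt_h = 0.5)
  bal <- prof$amounts_balance
  n <- nrow(bal)
  expect_equal(bal$body_ug[n], bal$absorbed_ug[n],
               tolerance = 1e-3)
  ratios <- prof$tissue_ug_per_mL[n, ] / prof$plasma_ug_per_mL[n]
  expect_equal(unname(ratios), rep(2, 13), tolerance = 1e-3)
})

test_that("profiles survive a CSV round trip", {
  phys <- build_physiology(study_subject("RIF"))
  params <- rescale_kp_to_vdss(compound_params("RIF"), phys)
  prof <- simulate_pbpk(params, phys, absorption_from_peff(1.3),
                        horizon_h = 24, dt_h = 1)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path, dose_ug = prof$dose_ug, api = "RIF")
  expect_equal(back$times_h, prof$times_h)
  expect_equal(back$plasma_ug_per_mL, prof$plasma_ug_per_mL, tolerance = 1e-6)
  expect_equal(back$tissue_ug_per_mL[, "Lung"],
               unname(prof$tissue_ug_per_mL[, "Lung"]), tolerance = 1e-6)
})

test_that("compound parameter files round-trip through CSV", {
  for (api in c("RIF", "ETH", "MOX")) {
    packaged <- system.file("extdata", paste0("compound_", api, ".csv"),
                            package = "lungdose")
    expect_true(nzchar(packaged))
    from_csv <- read_compound_params(packaged)
    builtin <- compound_params(api)
    expect_equal(from_csv$kp, builtin$kp)
    expect_equal(from_csv$cl_iv_L_per_h, builtin$cl_iv_L_per_h)
    expect_equal(from_csv$mw_salt, builtin$mw_salt)
    expect_equal(from_csv$dose_mg, builtin$dose_mg)
  }
})
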