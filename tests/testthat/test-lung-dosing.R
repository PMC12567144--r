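test_that("lung exposure equals Kp_lung * AUC_plasma * V_lung / dose on an
           analytic profile", {
  phys <- build_physiology(ref_subject())
  t <- seq(0, 72, by = 0.05)
  plasma <- oral_model_conc(t, "one-compartment-oral", dose = 100,
                            ka = 0.8, cl = 10, v = 40)  # mg/L = ug/mL
  kp_lung <- 3.5
  tissue <- matrix(kp_lung * plasma, ncol = 1,
                   dimnames = list(NULL, "Lung"))
  prof <- structure(list(api = "TOY", times_h = t,
                         plasma_ug_per_mL = plasma,
                         tissue_ug_per_mL = tissue, dose_ug = 100 * 1000),
                    class = "concentration_profile")
  auc_plasma <- nca(t, plasma)$auc_0_inf
  expected <- kp_lung * auc_plasma * phys$tissue_volumes[["Lung"]] * 1000 /
    (100 * 1000) * 100
  expect_equal(lung_exposure(prof, phys), expected, tolerance = 1e-6)
})

test_that("lung exposure is dose-invariant for the linear PBPK model", {
  phys <- build_physiology(study_subject("MOX"))
  params <- rescale_kp_to_vdss(compound_params("MOX"), phys)
  absorption <- absorption_from_peff(params$peff_1e4_cm_s)
  e1 <- lung_exposure(simulate_pbpk(params, phys, absorption,
                                    dose_mg = 200), phys)
  e2 <- lung_exposure(simulate_pbpk(params, phys, absorption,
                                    dose_mg = 400), phys)
  expect_equal(e1, e2, tolerance = 0.001)
})

test_that("lung exposure rejects profiles without lung data or dose", {
  phys <- build_physiology(ref_subject())
  prof <- structure(list(times_h = 0:10, plasma_ug_per_mL = rep(1, 11),
                         tissue_ug_per_mL = matrix(1, 11, 1,
                                                   dimnames = list(NULL, "Liver")),
                         dose_ug = 1000),
                    class = "concentration_profile")
  expect_error(lung_exposure(prof, phys), "no Lung")
  prof$tissue_ug_per_mL <- matrix(1, 11, 1, dimnames = list(NULL, "Lung"))
  prof$dose_ug <- 0
  expect_error(lung_exposure(prof, phys), "dose")
})

test_that("inhaled doses reproduce the published translation table", {
  expect_equal(inhaled_dose(1200, 13, 40)$inhaled_dose_mg, 390)
  expect_equal(inhaled_dose(400, 32.5, 40)$inhaled_dose_mg, 325)
  # printed value 25.65 traces to an unrounded exposure near 1.71%
  expect_equal(inhaled_dose(600, 1.7, 40)$inhaled_dose_mg, 25.5)
  expect_equal(inhaled_dose(600, 1.71, 40)$inhaled_dose_mg, 25.65)
  # tenth rule
  expect_equal(inhaled_dose(600, source = "literature-tenth-rule")$inhaled_dose_mg,
               60)
  expect_error(inhaled_dose(600, 1.7, 0))
  expect_error(inhaled_dose(600, 0, 40))
})

test_that("salt-aware molar ratios reproduce the published pairs", {
  mw_rif <- 822.94; mw_eth_salt <- 277.23; mw_mox_salt <- 437.9
  r_eth <- molar_ratio(25.65, mw_rif, 390, mw_eth_salt, "RIF", "ETH")
  expect_equal(r_eth$ratio_b_per_a, 45, tolerance = 0.01)
  r_mox <- molar_ratio(25.65, mw_rif, 325, mw_mox_salt, "RIF", "MOX")
  expect_equal(r_mox$ratio_b_per_a, 23.8, tolerance = 0.01)
  r_lit <- molar_ratio(150, mw_rif, 100, mw_mox_salt, "RIF", "MOX")
  expect_equal(r_lit$ratio_b_per_a, 1.25, tolerance = 0.01)
  expect_equal(format(r_mox), "1:23.8")
  # equal doses and equal molar masses are equimolar
  expect_equal(molar_ratio(10, 300, 10, 300)$ratio_b_per_a, 1)
})

test_that("molar-ratio reciprocity is exact", {
  cases <- list(c(25.65, 822.94, 390, 277.23),
                c(150, 822.94, 100, 437.9),
                c(7, 123.4, 11, 567.8))
  for (x in cases) {
    fwd <- molar_ratio(x[1], x[2], x[3], x[4])$ratio_b_per_a
    rev <- molar_ratio(x[3], x[4], x[1], x[2])$ratio_b_per_a
    expect_equal(fwd * rev, 1, tolerance = 1e-14)
  }
})

test_that("dose-normalised tissue mole ratio reproduces the independent check", {
  # lung concentrations per 100 mg oral dose: 2.3 ug/g at 600 mg, 16.2 at 400
  expect_equal(2.3 / 6, 0.38, tolerance = 0.01)
  expect_equal(16.2 / 4, 4.05)
  ratio <- tissue_ratio_check(0.38, 822.94, 4, 401.44)
  expect_equal(ratio, 21.6, tolerance = 0.005)
  expect_equal(ratio, 21.5, tolerance = 0.01)
})

test_that("capsule compositions match the dissolution-study doses", {
  lit <- capsule_composition(25, 1.25, 822.94, 437.9)
  expect_equal(lit$mass_a_mg, 15, tolerance = 0.5 / 15)
  expect_equal(lit$mass_b_mg, 10, tolerance = 0.5 / 10)
  model <- capsule_composition(25, 23.8, 822.94, 437.9)
  expect_equal(model$mass_a_mg, 2, tolerance = 0.5 / 2)
  expect_equal(model$mass_b_mg, 23, tolerance = 0.5 / 23)
  # conservation is exact and r = 0 sends everything to A
  expect_equal(lit$mass_a_mg + lit$mass_b_mg, 25)
  expect_equal(capsule_composition(25, 0, 822.94, 437.9)$mass_a_mg, 25)
})

test_that("capsule mass of the anchor API decreases strictly with the ratio", {
  rs <- c(0, 0.5, 1.25, 5, 23.8, 100)
  masses <- vapply(rs, function(r) {
    capsule_composition(25, r, 822.94, 437.9)$mass_a_mg
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
  sums <- vapply(rs, function(r) {
    comp <- capsule_composition(25, r, 822.94, 437.9)
    comp$mass_a_mg + comp$mass_b_mg
  }, numeric(1))
  expect_equal(sums, rep(25, length(rs)))
})
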