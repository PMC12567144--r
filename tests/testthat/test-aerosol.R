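test_that("impactor metrics follow the emitted/recovered definitions", {
  run <- impactor_run(7500, 5000, 5000, 12500)  # ug
  m <- aerosol_metrics(run)
  expect_equal(m$recovered_dose_mg, 30)
  expect_equal(m$ef_percent, 75)
  expect_equal(m$emitted_dose_mg, 22.5)
  expect_equal(m$fpm_mg, 12.5)
  expect_equal(m$fpf_percent, 100 * 12.5 / 22.5, tolerance = 1e-12)
})

test_that("impactor metric edge cases behave as defined", {
  # all mass in the device: EF 0, FPF warned down to 0
  expect_warning(m0 <- aerosol_metrics(impactor_run(10000, 0, 0, 0)),
                 "zero emitted")
  expect_equal(m0$ef_percent, 0)
  expect_equal(m0$fpf_percent, 0)
  # filter-only deposition: EF and FPF both 100
  m1 <- aerosol_metrics(impactor_run(0, 0, 0, 8000))
  expect_equal(m1$ef_percent, 100)
  expect_equal(m1$fpf_percent, 100)
  expect_error(impactor_run(0, 0, 0, 0), "positive")
})

test_that("EF and FPF stay within [0, 100] and FPM below emitted dose for
           arbitrary non-negative stage masses", {
  set.seed(42)
  for (i in 1:200) {
    masses <- stats::rexp(4, rate = 1e-3) * stats::rbinom(4, 1, 0.8)
    if (sum(masses) == 0) masses[1] <- 1
    m <- suppressWarnings(aerosol_metrics(impactor_run(masses[1], masses[2],
                                                       masses[3], masses[4])))
    expect_gte(m$ef_percent, 0); expect_lte(m$ef_percent, 100)
    expect_gte(m$fpf_percent, 0); expect_lte(m$fpf_percent, 100)
    expect_lte(m$fpm_mg, m$emitted_dose_mg + 1e-12)
    expect_lte(m$emitted_dose_mg, m$recovered_dose_mg)
  }
})

test_that("content uniformity applies the label-claim and RSD criteria", {
  ten_same <- content_uniformity(rep(95.7, 10))
  expect_equal(ten_same$rsd_percent, 0)
  expect_true(ten_same$uniformity_pass)
  expect_true(ten_same$homogeneity_pass)

  # high scatter: mean inside the band but RSD above the homogeneity limit
  set.seed(7)
  scattered <- 92.8 * (1 + 0.118 * scale(stats::rnorm(10))[, 1])
  res <- content_uniformity(scattered)
  expect_equal(res$mean, 92.8, tolerance = 1e-6)
  expect_equal(res$rsd_percent, 11.8, tolerance = 0.02)
  expect_true(res$uniformity_pass)
  expect_false(res$homogeneity_pass)

  expect_false(content_uniformity(rep(83, 5))$uniformity_pass)
  expect_error(content_uniformity(100), "at least 2")
})

test_that("PSD summary computes quantiles, SPAN and SMD as defined", {
  # near-monodisperse 3 um
  mono <- psd_summary(c(2.999, 3.001), 1)
  expect_equal(mono$x50, 3, tolerance = 1e-3)
  expect_equal(mono$span, 0, tolerance = 1e-3)
  expect_equal(mono$smd, 3, tolerance = 1e-3)
  expect_equal(mono$frac_below_5um, 100)

  # two equal bins with geometric-mean diameters 2 and 4 um: the SMD is the
  # harmonic mean 1/(0.5/2 + 0.5/4) = 2.67 um
  two <- psd_summary(sqrt(2) * c(1, 2, 4), c(0.5, 0.5))
  expect_equal(two$smd, 8 / 3, tolerance = 1e-12)

  # SPAN from the reported spray-dried 1:45 quantiles
  expect_equal(psd_span(1.30, 3.77, 7.23), 1.57, tolerance = 0.005)

  expect_error(psd_summary(c(1, 2, 3), c(0.6, 0.6)), "sum to 1")
  expect_error(psd_summary(c(2, 1, 3), c(0.5, 0.5)), "increasing")
})

test_that("PSD quantiles are order-preserving under monotone edge rescaling", {
  edges <- c(0.5, 1, 2, 4, 8, 16)
  fr <- c(0.1, 0.25, 0.3, 0.25, 0.1)
  base <- psd_summary(edges, fr)
  scaled <- psd_summary(edges * 2.5, fr)
  expect_equal(scaled$x10, 2.5 * base$x10)
  expect_equal(scaled$x50, 2.5 * base$x50)
  expect_equal(scaled$x90, 2.5 * base$x90)
  expect_true(base$x10 <= base$x50 && base$x50 <= base$x90)
  expect_equal(scaled$span, base$span, tolerance = 1e-12)
})

test_that("dissolution correction reduces to C*V/dose without withdrawals", {
  conc <- c(0, 10, 20, 30, 35, 36, 36, 36, 36)
  run <- dissolution_run(sampled_conc_ug_per_mL = conc, dose_ug = 2000,
                         sample_volume_mL = 0)
  prof <- dissolution_profile(run)
  expect_equal(prof$percent_dissolved, 100 * conc * 55 / 2000)
})

test_that("the withdrawal correction adds back the removed drug", {
  # constant concentration at dose/V: each aliquot removes drug, so the
  # corrected cumulative exceeds 100% by the replaced fraction
  dose <- 5500; V <- 55; v <- 1
  conc <- rep(dose / V, 3)
  run <- dissolution_run(times_min = c(0, 2, 5),
                         sampled_conc_ug_per_mL = conc, dose_ug = dose,
                         vessel_volume_mL = V, sample_volume_mL = v)
  prof <- dissolution_profile(run)
  expect_equal(prof$percent_dissolved,
               100 * c(1, 1 + v / V, 1 + 2 * v / V))
})

test_that("a declining corrected series warns rather than fails", {
  run <- dissolution_run(times_min = c(0, 2, 5, 10),
                         sampled_conc_ug_per_mL = c(10, 30, 25, 20),
                         dose_ug = 2000)
  expect_warning(prof <- dissolution_profile(run), "not monotone")
  expect_equal(nrow(prof), 4)
})
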