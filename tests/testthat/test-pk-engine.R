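rif <- rifampicin_model()
phys <- default_physiology()

test_that("absorption chain rates follow the permeability relations", {
  ap <- absorption_params(rif$compound, phys)
  # ka = 2 * 1e-4 cm/s / 1.75 cm * 3600 s/h
  expect_equal(ap$ka, 2e-4 / 1.75 * 3600, tolerance = 1e-12)
  expect_equal(ap$kt, 7 / 3.32, tolerance = 1e-12)
  # Fa = 1 - (kt/(kt+ka))^n for the pure first-order chain
  expect_equal(ap$fa_closed_form,
               1 - (ap$kt / (ap$kt + ap$ka))^7, tolerance = 1e-12)
  expect_equal(ap$fa_closed_form, 0.713, tolerance = 0.001)

  cpd0 <- rif$compound
  cpd0$peff <- 0
  expect_equal(absorption_params(cpd0, phys)$fa_closed_form, 0)
})

test_that("simulated fraction absorbed matches the transit-chain closed form", {
  prof <- simulate_pk(rif, dose_regimen("oral", 600), phys, t_end = 48,
                      dt_out = 0.1)
  ap <- absorption_params(rif$compound, phys)
  expect_equal(fraction_absorbed(prof), ap$fa_closed_form, tolerance = 0.01)

  # peff = 0: nothing is absorbed, the whole dose exits the chain
  cpd0 <- rif
  cpd0$compound$peff <- 0
  prof0 <- simulate_pk(cpd0, dose_regimen("oral", 600), phys, t_end = 48,
                       dt_out = 0.1)
  expect_equal(fraction_absorbed(prof0), 0, tolerance = 1e-6)
  expect_equal(tail(prof0$eliminated$unabsorbed, 1), 600, tolerance = 0.01)

  # IV profiles carry no absorption bookkeeping
  iv <- simulate_pk(rif, dose_regimen("iv_bolus", 600), phys, t_end = 12)
  expect_error(fraction_absorbed(iv), "oral")
})

test_that("baseline clearance recovers dose/AUC and the published partition", {
  # total baseline plasma CL = (0.0179 + 0.0623 + 0.0169) L/h/kg * 70 kg
  cl_expected <- (0.0179 + 0.0623 + 0.0169) * 70
  expect_equal(cl_expected, 6.797)
  prof <- simulate_pk(rif, dose_regimen("iv_bolus", 1), phys, t_end = 48,
                      dt_out = 0.02)
  nca <- run_nca(prof, dose = 1)
  expect_equal(1 / nca$auc_inf, cl_expected, tolerance = 1e-3)
  # renal component is consistent with fup * GFR (residual reflects the
  # GFR assumption behind the fixture's 0.0169)
  expect_equal(rif$compound$fup * phys$gfr / phys$body_weight, 0.01646,
               tolerance = 1e-3)
  expect_equal(rif$clearance$cl_renal, 0.0169, tolerance = 0.03)
})

test_that("with all clearances zero the dose is conserved in the body", {
  inert <- rif
  inert$clearance$cl_cyp3a4_hepatic <- 0
  inert$clearance$cl_other_hepatic <- 0
  inert$clearance$cl_renal <- 0
  prof <- simulate_pk(inert, dose_regimen("iv_bolus", 100), phys, t_end = 96,
                      dt_out = 0.5)
  expect_equal(max(abs(prof$in_body - 100)), 0, tolerance = 1e-4)
})

test_that("IV bolus initial concentration equals dose / (Vc * BW)", {
  prof <- simulate_pk(rif, dose_regimen("iv_bolus", 600), phys, t_end = 6)
  expect_equal(prof$conc[1], 600 / (0.15145 * 70), tolerance = 1e-8)
})

test_that("ODE engine matches the closed-form two-compartment oracle", {
  times <- seq(0, 24, by = 0.05)
  num <- simulate_pk(rif, dose_regimen("iv_bolus", 600), phys, t_end = 24)
  ana <- analytic_two_compartment_iv(rif$disposition, 6.797, 600, 70,
                                     num$times)
  expect_lt(max(abs(num$conc - ana$conc) / ana$conc), 1e-6)

  # degenerate one-compartment: k12 = k21 = 0 is mono-exponential
  disp1 <- list(vc = 0.5, k12 = 0, k21 = 0)
  a1 <- analytic_two_compartment_iv(disp1, 7, 100, 70, times)
  k10 <- 7 / (0.5 * 70)
  expect_equal(a1$conc, 100 / (0.5 * 70) * exp(-k10 * times),
               tolerance = 1e-12)

  # AUC(0-inf) = dose / CL regardless of the distribution constants
  for (k in list(c(0.3, 0.9), c(2, 0.4))) {
    disp <- list(vc = 0.2, k12 = k[1], k21 = k[2])
    tt <- seq(0, 400, by = 0.02)
    a <- analytic_two_compartment_iv(disp, 3.5, 250, 70, tt)
    expect_equal(auc_interval(a, method = "linear"), 250 / 3.5,
                 tolerance = 1e-3)
  }

  expect_error(
    analytic_two_compartment_iv(list(vc = 1, k12 = 0, k21 = 0, k13 = 0.1,
                                     k31 = 0.1), 7, 100, 70, times),
    "two compartments")
})

test_that("mass balance holds within 0.1% across routes and regimens", {
  runs <- list(
    simulate_pk(rif, dose_regimen("iv_bolus", 600), phys, t_end = 24),
    simulate_pk(rif, dose_regimen("iv_infusion", 600, infusion_duration = 1),
                phys, t_end = 24),
    simulate_pk(rif, dose_regimen("oral", 600), phys, t_end = 48,
                dt_out = 0.1),
    simulate_pk(rif, dose_regimen("oral", 600, n_doses = 4, interval = 24),
                phys, t_end = 120, dt_out = 0.1, autoinduction = TRUE)
  )
  for (p in runs) expect_lt(mass_balance_error(p), 1e-3)
})

test_that("AUC is dose-proportional for linear clearance", {
  aucs <- vapply(c(6, 600), function(d) {
    p <- simulate_pk(rif, dose_regimen("iv_bolus", d), phys, t_end = 48,
                     dt_out = 0.02)
    run_nca(p, dose = d)$auc_inf
  }, numeric(1))
  expect_equal(aucs[2] / aucs[1], 100, tolerance = 1e-6)
})

test_that("multiple dosing obeys superposition in the linear case", {
  single <- simulate_pk(rif, dose_regimen("oral", 300), phys, t_end = 96,
                        dt_out = 0.1)
  multi <- simulate_pk(rif, dose_regimen("oral", 300, n_doses = 3,
                                         interval = 12),
                       phys, t_end = 96, dt_out = 0.1)
  # sum of shifted single-dose profiles on the common grid
  shifted <- approx(single$times, single$conc, xout = multi$times,
                    yleft = 0, rule = 2)$y +
    approx(single$times + 12, single$conc, xout = multi$times, yleft = 0,
           rule = 2)$y +
    approx(single$times + 24, single$conc, xout = multi$times, yleft = 0,
           rule = 2)$y
  scale <- max(shifted)
  expect_lt(max(abs(multi$conc - shifted)) / scale, 1e-4)
})

test_that("michaelis-menten mode reduces to the linear clearance below Km", {
  mm <- rif
  mm$clearance$vmax_mode <- "michaelis_menten"
  # microdose keeps concentrations well below Km = 0.028 mg/L
  p_mm <- simulate_pk(mm, dose_regimen("iv_bolus", 0.01), phys, t_end = 48,
                      dt_out = 0.02)
  p_lin <- simulate_pk(rif, dose_regimen("iv_bolus", 0.01), phys, t_end = 48,
                       dt_out = 0.02)
  auc_mm <- run_nca(p_mm, dose = 0.01)$auc_inf
  auc_lin <- run_nca(p_lin, dose = 0.01)$auc_inf
  expect_equal(auc_mm, auc_lin, tolerance = 0.02)
  # at therapeutic concentrations the saturable pathway clears less
  p_hi <- simulate_pk(mm, dose_regimen("iv_bolus", 600), phys, t_end = 48,
                      dt_out = 0.02)
  expect_gt(run_nca(p_hi, dose = 600)$auc_inf,
            run_nca(simulate_pk(rif, dose_regimen("iv_bolus", 600), phys,
                                t_end = 48, dt_out = 0.02),
                    dose = 600)$auc_inf)
})

test_that("regimen construction enforces its invariants", {
  expect_error(dose_regimen("oral", 0), "dose")
  expect_error(dose_regimen("oral", 100, n_doses = 3, interval = -1),
               "interval")
  expect_error(dose_regimen("iv_infusion", 100), "infusion_duration")
  expect_error(simulate_pk(rif, dose_regimen("oral", 100, start_time = 100),
                           phys, t_end = 50), "cover")
})
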