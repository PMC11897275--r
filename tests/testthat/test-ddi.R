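rif <- rifampicin_model()
phys <- default_physiology()

test_that("design strings from the panel parse into sensible defaults", {
  d <- default_design("10 mg, SD")
  expect_equal(d$victim_regimen$dose, 10)
  expect_equal(d$victim_regimen$n_doses, 1L)
  expect_equal(d$victim_regimen$start_time, 7 * 24)
  expect_false(d$steady_state_victim)
  expect_gte(d$perpetrator_regimen$n_doses * 24, d$t_end)

  d2 <- default_design("1,000 mg, SD")
  expect_equal(d2$victim_regimen$dose, 1000)
  d3 <- default_design("500 ug, SD")
  expect_equal(d3$victim_regimen$dose, 0.5)
  dq <- default_design("10 mg, QD")
  expect_true(dq$steady_state_victim)
  expect_equal(diff(dq$auc_window), 24)
  expect_error(default_design("abc"), "parse")
})

test_that("null perpetrator and non-substrate victim give AUCR = 1", {
  d <- default_design("20 mg, SD", washin_days = 4, post_dose_h = 96)
  rif0 <- rif
  rif0$induction$emax <- 0
  r0 <- run_ddi(make_test_victim(0.6, fg = 0.8), rif0, d, phys, dt_out = 0.2)
  expect_equal(r0$aucr, 1, tolerance = 1e-3)
  expect_equal(r0$cmaxr, 1, tolerance = 1e-3)

  r1 <- run_ddi(make_test_victim(0, fg = 1), rif, d, phys, dt_out = 0.2)
  expect_equal(r1$aucr, 1, tolerance = 1e-3)
  expect_equal(r1$cmaxr, 1, tolerance = 1e-3)

  expect_error(run_ddi(make_test_victim(0.5), make_test_victim(0.2), d, phys),
               "induction")
})

test_that("dynamic AUCR matches the analytic clearance-scaling oracle", {
  d14 <- default_design("50 mg, SD", washin_days = 14)
  for (v in exemplar_victims()) {
    r <- run_ddi(v, rif, d14, phys, dt_out = 0.2)
    a <- aucr_analytic(v$clearance$fm_cyp3a4, v$clearance$fg,
                       r$fold_liver_mean, r$fold_gut_mean)
    expect_lt(abs(r$aucr / a - 1), 0.15)
    expect_false(r$extrapolation_warning)
    expect_lte(r$aucr, 1 + 1e-6) # pure inducer cannot raise exposure
  }
})

test_that("AUCR responds monotonically to fm and washin duration", {
  d7 <- default_design("50 mg, SD")
  aucr_fm <- vapply(c(0.25, 0.6, 0.95), function(fm) {
    run_ddi(make_test_victim(fm), rif, d7, phys, dt_out = 0.25)$aucr
  }, numeric(1))
  expect_true(all(diff(aucr_fm) < 0))

  d2 <- default_design("50 mg, SD", washin_days = 2)
  shorter <- run_ddi(make_test_victim(0.6), rif, d2, phys, dt_out = 0.25)
  expect_gt(shorter$aucr, aucr_fm[2]) # less washin, less induction
})

test_that("steady-state QD victims are evaluated over a dosing interval", {
  dq <- default_design("10 mg, QD", washin_days = 4, victim_qd_doses = 6)
  r <- run_ddi(make_test_victim(0.6, fg = 0.9), rif, dq, phys, dt_out = 0.25)
  expect_true(r$aucr > 0 && r$aucr < 1)
  expect_true(r$cmaxr > 0 && r$cmaxr < 1)
})

test_that("the analytic oracle reproduces its hand-computed cases", {
  expect_equal(aucr_analytic(0, 1, 4), 1)
  expect_equal(aucr_analytic(1, 1, 2), 0.5)
  expect_equal(aucr_analytic(0.8, 1, 4), 1 / (0.2 + 0.8 * 4),
               tolerance = 1e-12)
  expect_equal(aucr_analytic(0.9, 0.5, 5), 0.0725, tolerance = 0.001)
  # inversion round trip
  for (fm in c(0.1, 0.5, 0.9)) {
    a <- aucr_analytic(fm, 0.7, 3.5, 2)
    expect_equal(fm_from_aucr_analytic(a, 0.7, 3.5, 2), fm,
                 tolerance = 1e-6)
  }
  expect_true(is.na(fm_from_aucr_analytic(0.5, 1, 1))) # no induction
})
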