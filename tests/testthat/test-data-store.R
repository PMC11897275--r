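test_that("rifampicin config loads with the published parameter values", {
  rif <- rifampicin_model()
  expect_s3_class(rif, "drug_model")
  expect_equal(rif$induction$emax, 14.6)
  expect_equal(rif$induction$ec50, 0.8)
  expect_equal(rif$compound$fup, 0.16)
  expect_equal(rif$compound$rbp, 0.52)
  expect_equal(rif$compound$molecular_weight, 822.96)
  expect_equal(rif$disposition$vc, 0.15145)
  expect_equal(rif$clearance$cl_cyp3a4_hepatic, 0.0179)
  expect_equal(rif$clearance$cl_other_hepatic, 0.0623)
  expect_equal(rif$clearance$cl_renal, 0.0169)
})

test_that("drug model validation rejects invariant violations", {
  rif <- rifampicin_model()
  bad <- unclass(rif)
  bad$compound$fup <- 0
  expect_error(do.call(drug_model, bad), "fup")
  bad <- unclass(rif)
  bad$compound$molecular_weight <- NULL
  expect_error(do.call(drug_model, bad), "molecular_weight")
  bad <- unclass(rif)
  bad$disposition$k13 <- 0.5 # k31 missing
  expect_error(do.call(drug_model, bad), "k13")
  bad <- unclass(rif)
  bad$clearance$vmax_mode <- "michaelis_menten"
  bad$clearance$km <- NULL
  expect_error(do.call(drug_model, bad), "km")
  bad <- unclass(rif)
  bad$clearance$fm_cyp3a4 <- 0.9 # inconsistent with partition (0.184)
  expect_error(do.call(drug_model, bad), "inconsistent")
})

test_that("yaml and json configs load identically", {
  rif <- rifampicin_model()
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(rif), yml)
  # yaml serialization trims trailing digits of derived quantities
  expect_equal(load_drug_model(yml), rif, tolerance = 1e-6)
})

test_that("interaction table has the published panel structure", {
  tab <- load_ddi_table()
  expect_equal(nrow(tab), 28L)
  expect_equal(sum(grepl("SD", tab$dosing)), 26L)
  expect_setequal(tab$victim[grepl("QD", tab$dosing)],
                  c("Macitentan", "Vorapaxar"))
  abi <- tab[tab$victim == "Abiraterone", ]
  expect_equal(abi$observed_aucr, 0.42)
  expect_equal(abi$predicted_aucr_static, 0.04)
  expect_equal(abi$predicted_aucr_pbpk, 0.22)
  # vorapaxar is the only victim with observed AUCR above 1
  expect_equal(tab$victim[tab$observed_aucr > 1], "Vorapaxar")
  expect_true(all(tab$observed_aucr > 0))
})

test_that("rifampicin PK validation table carries the IV anchor rows", {
  pk <- load_pk_validation_table()
  iv <- pk[pk$regimen_label == "600 mg IV SD", ]
  expect_equal(iv$predicted[iv$parameter == "Cmax"], 31.9)
  expect_equal(iv$observed[iv$parameter == "Cmax"], 37.6)
  expect_equal(iv$predicted[iv$parameter == "AUC"], 93.73)
  expect_equal(iv$observed[iv$parameter == "AUC"], 114)
  expect_equal(iv$predicted[iv$parameter == "T1/2"], 2.22)
  expect_equal(iv$observed[iv$parameter == "T1/2"], 2.21)
  oral200 <- pk[pk$regimen_label == "200 mg oral SD" & pk$parameter == "AUC", ]
  expect_equal(oral200$predicted, 49.6)
  expect_equal(oral200$observed, 60)
})

test_that("profile CSV round trip is identity and rejects bad input", {
  p <- conc_profile(c(0, 0.5, 1, 2), c(0, 3.25, 5.0, 2.125))
  f <- tempfile(fileext = ".csv")
  write_profile(p, f)
  expect_identical(readLines(f, n = 1L), "time_h,conc_mg_per_L")
  q <- read_profile(f)
  expect_equal(q$times, p$times, tolerance = 1e-12)
  expect_equal(q$conc, p$conc, tolerance = 1e-12)

  # irrational values survive the 15-significant-digit text round trip
  p2 <- conc_profile(c(0, pi, 4), exp(c(-0.1, -1, -2.3)))
  write_profile(p2, f)
  expect_equal(read_profile(f)$conc, p2$conc, tolerance = 1e-13)

  expect_error(conc_profile(numeric(0), numeric(0)), "empty")
  expect_error(conc_profile(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(read_profile(tempfile()), "no such profile")
})

test_that("exemplar victims are valid, induction-free, and span fm", {
  vs <- exemplar_victims()
  expect_length(vs, 3L)
  expect_true(all(vapply(vs, function(v) is.null(v$induction), logical(1))))
  expect_equal(unname(vapply(vs, function(v) v$clearance$fm_cyp3a4,
                             numeric(1))),
               c(0.25, 0.60, 0.95))
})
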