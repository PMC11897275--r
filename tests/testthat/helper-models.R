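# shared builders for tests: a minimal linear victim with a chosen CYP3A4
# contribution and gut availability
make_test_victim <- function(fm, fg = 1, cl_total = 0.1, vc = 1, peff = 3,
                             name = sprintf("test-victim-fm%.2f", fm)) {
  drug_model(
    name = name,
    compound = list(molecular_weight = 400, log_d = 2, pka_values = list(),
                    aqueous_solubility = 10, solubility_ph = 7,
                    particle_radius = 25, precipitation_time = 900,
                    peff = peff, rbp = 1, fup = 0.1),
    disposition = list(vc = vc, k12 = 0, k21 = 0),
    clearance = list(cl_cyp3a4_hepatic = fm * cl_total,
                     cl_other_hepatic = (1 - fm) * cl_total,
                     cl_renal = 0, vmax_mode = "linear",
                     fm_cyp3a4 = fm, fg = fg)
  )
}
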