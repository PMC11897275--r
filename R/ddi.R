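# Victim/perpetrator co-simulation: paired runs (victim alone vs victim under
# rifampicin with enzyme dynamics coupled) and the AUCR/CmaxR arithmetic.

#' Build a DDI study design from a dosing-method string
#'
#' Parses a dosing method of the form `"<dose> mg, SD"`, `"<dose> ug, SD"`
#' or `"<dose> mg, QD"` (the format of the packaged interaction table) and
#' returns the default study design: the perpetrator given 600 mg orally
#' once daily for `washin_days` of pre-treatment and then throughout, the
#' victim given as a single dose with the next perpetrator dose (SD) or once
#' daily to steady state with the interval AUC evaluated over the last
#' dosing interval (QD).
#'
#' @param victim_dosing Dosing string, e.g. `"10 mg, SD"` or
#'   `"1,000 mg, SD"`.
#' @param washin_days Days of perpetrator pre-treatment before the first
#'   victim dose (default 7).
#' @param perp_dose Perpetrator dose (mg, oral QD; default 600).
#' @param post_dose_h Observation window after a single victim dose (h,
#'   default 144 = 6 days).
#' @param victim_qd_doses Number of once-daily victim doses for steady-state
#'   designs (default 10).
#' @return An object of class `ddi_design` with elements
#'   `perpetrator_regimen`, `victim_regimen`, `washin_days`, `t_end`,
#'   `steady_state_victim`, `auc_window`.
#' @examples
#' default_design("10 mg, SD")
#' @export
default_design <- function(victim_dosing, washin_days = 7, perp_dose = 600,
                           post_dose_h = 144, victim_qd_doses = 10) {
  stopifnot(washin_days >= 0)
  m <- regmatches(victim_dosing,
                  regexec("^\\s*([0-9][0-9.,]*)\\s*(mg|ug)\\s*,\\s*(SD|QD)\\s*$",
                          victim_dosing))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse dosing method '%s'", victim_dosing),
         call. = FALSE)
  }
  dose <- as.numeric(gsub(",", "", m[2]))
  if (m[3] == "ug") dose <- dose / 1000
  qd <- m[4] == "QD"
  victim_start <- washin_days * 24
  if (qd) {
    victim_regimen <- dose_regimen("oral", dose, n_doses = victim_qd_doses,
                                   interval = 24, start_time = victim_start)
    t_end <- victim_start + victim_qd_doses * 24
    auc_window <- c(victim_start + (victim_qd_doses - 1) * 24, t_end)
  } else {
    victim_regimen <- dose_regimen("oral", dose, start_time = victim_start)
    t_end <- victim_start + post_dose_h
    auc_window <- c(victim_start, t_end)
  }
  perp_regimen <- dose_regimen("oral", perp_dose,
                               n_doses = ceiling(t_end / 24), interval = 24)
  structure(list(perpetrator_regimen = perp_regimen,
                 victim_regimen = victim_regimen,
                 washin_days = washin_days, t_end = t_end,
                 steady_state_victim = qd, auc_window = auc_window),
            class = "ddi_design")
}

#' @export
print.ddi_design <- function(x, ...) {
  cat("<ddi_design>\n  perpetrator: "); print(x$perpetrator_regimen)
  cat("  victim:      "); print(x$victim_regimen)
  cat(sprintf("  washin %g days; t_end %g h; victim at steady state: %s\n",
              x$washin_days, x$t_end, x$steady_state_victim))
  invisible(x)
}

# exposure metrics for one arm: AUC (0-inf for single dose via lambda-z
# extrapolation, interval AUC at steady state otherwise) and window Cmax
arm_exposure <- function(profile, design, victim_dose, window) {
  w <- clip_profile(profile, window[1], window[2], shift = TRUE)
  if (design$steady_state_victim) {
    list(auc = auc_trapezoid(w$times, w$conc), cmax = max(w$conc),
         extrap_warn = FALSE)
  } else {
    nca <- run_nca(w, dose = victim_dose)
    auc <- if (nca$lambda_z_estimable) nca$auc_inf else nca$auc_last
    list(auc = auc, cmax = nca$cmax,
         extrap_warn = !nca$lambda_z_estimable ||
           (is.finite(nca$extrap_pct) && nca$extrap_pct > 20))
  }
}

#' Run a paired victim/perpetrator interaction simulation
#'
#' Simulates the victim twice — alone, and co-administered with the
#' perpetrator with CYP3A4 enzyme turnover coupled (including the
#' perpetrator's autoinduction of its own CYP3A4 pathway) — and returns the
#' AUC and Cmax ratios. Single-dose victims use AUC(0-inf) by lambda-z
#' extrapolation; steady-state victims use the AUC over the final dosing
#' interval.
#'
#' @param victim Victim [drug_model()] (no induction block; `fm_cyp3a4` and
#'   `fg` define its CYP3A4 liability).
#' @param perpetrator Perpetrator [drug_model()] with an induction block.
#' @param design A [default_design()] object.
#' @param phys A [default_physiology()].
#' @param dt_out Output grid (h), default 0.1.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `ddi_result`: `aucr`, `cmaxr`, the per-arm
#'   AUCs/Cmaxs, enzyme-fold diagnostics at and averaged after the victim
#'   dose (`fold_liver_at_victim_dose`, `fold_gut_at_victim_dose`,
#'   `fold_liver_mean`, `fold_gut_mean`), and `extrapolation_warning`.
#' @export
run_ddi <- function(victim, perpetrator, design, phys = default_physiology(),
                    dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(victim, "drug_model"), inherits(design, "ddi_design"))
  if (is.null(perpetrator$induction)) {
    stop("perpetrator must carry induction parameters", call. = FALSE)
  }
  victim_start <- design$victim_regimen$start_time
  window <- design$auc_window
  vdose <- design$victim_regimen$dose

  # victim alone, same regimen shifted to t = 0
  alone_reg <- design$victim_regimen
  alone_reg$start_time <- 0
  alone <- simulate_pk(victim, alone_reg, phys,
                       t_end = design$t_end - victim_start, dt_out = dt_out,
                       rtol = rtol, atol = atol)
  alone_m <- arm_exposure(alone, design, vdose, window - victim_start)

  # co-simulation with shared enzyme pool
  sys <- make_system(list(perpetrator = list(drug = perpetrator,
                                             regimen = design$perpetrator_regimen),
                          victim = list(drug = victim,
                                        regimen = design$victim_regimen)),
                     phys, induction_active = TRUE, autoinduction = TRUE)
  out <- integrate_system(sys, design$t_end, dt_out, rtol, atol)
  combo <- extract_profile(sys, out, "victim")
  combo_m <- arm_exposure(combo, design, vdose, window)

  enz <- combo$enzyme
  at_dose <- which.min(abs(enz$time - victim_start))
  in_win <- enz$time >= window[1] & enz$time <= window[2]
  # effective liver fold: victim-concentration-weighted mean enzyme state
  # (the exact scaling factor of the liver CYP3A4 pathway for a linear victim)
  cw <- combo$conc[in_win]
  fold_liver_eff <- if (sum(cw) > 0) {
    sum(enz$e_rel_liver[in_win] * cw) / sum(cw)
  } else mean(enz$e_rel_liver[in_win])
  # effective gut fold: invert the realized intestinal availability of the
  # combo arm, Fg' = (absorbed - gut extracted) / absorbed
  fg0 <- victim$clearance$fg
  absorbed <- combo$dose_total - tail(combo$eliminated$unabsorbed, 1L)
  fold_gut_eff <- if (fg0 < 1 && absorbed > 0) {
    fgp <- (absorbed - tail(combo$gut_extracted, 1L)) / absorbed
    fg0 * (1 - fgp) / (fgp * (1 - fg0))
  } else mean(enz$e_rel_gut[in_win])
  res <- list(
    aucr = combo_m$auc / alone_m$auc,
    cmaxr = combo_m$cmax / alone_m$cmax,
    auc_alone = alone_m$auc, auc_combo = combo_m$auc,
    cmax_alone = alone_m$cmax, cmax_combo = combo_m$cmax,
    fold_liver_at_victim_dose = enz$e_rel_liver[at_dose],
    fold_gut_at_victim_dose = enz$e_rel_gut[at_dose],
    fold_liver_mean = fold_liver_eff,
    fold_gut_mean = fold_gut_eff,
    extrapolation_warning = alone_m$extrap_warn || combo_m$extrap_warn
  )
  structure(res, class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> AUCR %.3f | CmaxR %.3f\n", x$aucr, x$cmaxr))
  cat(sprintf("  AUC alone/combo: %.4g / %.4g ug.h/mL\n",
              x$auc_alone, x$auc_combo))
  cat(sprintf("  enzyme fold at victim dose: liver %.2f, gut %.2f\n",
              x$fold_liver_at_victim_dose, x$fold_gut_at_victim_dose))
  if (x$extrapolation_warning) cat("  warning: AUC extrapolation > 20%\n")
  invisible(x)
}

#' Closed-form AUCR for a linear victim at constant induction
#'
#' Clearance-scaling oracle for linear, low-extraction victims once the
#' enzyme has reached steady state: the liver pathway scales by the liver
#' fold and the intestinal availability drops from `fg` to `fg'`, giving
#' \deqn{AUCR = \frac{f_g'/f_g}{(1 - f_m) + f_m \cdot fold_{liver}}}
#' with `fg' = fg / (fg + (1 - fg) * fold_gut)`.
#'
#' @param fm Victim CYP3A4 fraction, `[0, 1]`.
#' @param fg Victim baseline intestinal availability, `(0, 1]`.
#' @param fold_liver Liver enzyme fold (>= 0).
#' @param fold_gut Gut enzyme fold (default `fold_liver`).
#' @return AUCR (in `(0, 1]` for folds >= 1).
#' @examples
#' aucr_analytic(fm = 0.9, fg = 0.5, fold_liver = 5) # 0.0725
#' @export
aucr_analytic <- function(fm, fg, fold_liver, fold_gut = fold_liver) {
  stopifnot(fm >= 0, fm <= 1, fg > 0, fg <= 1, fold_liver >= 0,
            fold_gut >= 0)
  fg_prime <- induced_fg(fg, fold_gut)
  (fg_prime / fg) / ((1 - fm) + fm * fold_liver)
}

#' Recover fm from an observed AUCR via the analytic model
#'
#' Inverts [aucr_analytic()] for `fm` by bisection (the AUCR is strictly
#' decreasing in `fm` for folds > 1). Returns `NA` when the AUCR is outside
#' the attainable range for the given folds.
#'
#' @param aucr Observed or simulated AUCR, > 0.
#' @inheritParams aucr_analytic
#' @return Estimated `fm` in `[0, 1]`, or `NA`.
#' @export
fm_from_aucr_analytic <- function(aucr, fg, fold_liver,
                                  fold_gut = fold_liver) {
  stopifnot(aucr > 0)
  if (fold_liver <= 1) return(NA_real_)
  f <- function(fm) aucr_analytic(fm, fg, fold_liver, fold_gut) - aucr
  if (f(0) < 0 || f(1) > 0) return(NA_real_)
  uniroot(f, c(0, 1), tol = 1e-10)$root
}
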