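# FDA-guidance mechanistic static model for induction-mediated AUCR
# prediction, used as the comparator to the dynamic co-simulation.

#' Intestinal perpetrator concentration for the static model
#'
#' Guidance convention: the dose dissolved in 250 mL,
#' `Igut = dose / MW / 0.25 L`, in uM.
#'
#' @param dose Perpetrator oral dose (mg), >= 0.
#' @param mw Molecular weight (g/mol), > 0.
#' @return Intestinal concentration (uM).
#' @examples
#' gut_concentration(600, 822.96) # ~2916 uM
#' @export
gut_concentration <- function(dose, mw) {
  if (mw <= 0) stop("mw must be > 0", call. = FALSE)
  stopifnot(dose >= 0)
  dose / mw / 0.25 * 1000
}

#' Unbound hepatic inlet perpetrator concentration
#'
#' Guidance convention:
#' `Ih = fup * (Cmax + Fa * Fg * ka * dose / Qh / Rb)`, converted to uM via
#' the molecular weight. The absorption term adds the portal contribution of
#' an oral dose to the systemic Cmax.
#'
#' @param cmax Steady-state systemic Cmax (mg/L).
#' @param dose Oral dose (mg).
#' @param fa Fraction absorbed.
#' @param fg Intestinal availability.
#' @param ka First-order absorption rate (1/h).
#' @param qh Hepatic blood flow (L/h).
#' @param rbp Blood/plasma concentration ratio.
#' @param fup Fraction unbound in plasma.
#' @param mw Molecular weight (g/mol).
#' @return Unbound hepatic inlet concentration (uM).
#' @export
hepatic_inlet_unbound <- function(cmax, dose, fa, fg, ka, qh, rbp, fup, mw) {
  stopifnot(mw > 0, qh > 0, rbp > 0)
  fup * (cmax + fa * fg * ka * dose / qh / rbp) / mw * 1000
}

#' Mechanistic static AUC-ratio prediction
#'
#' The guidance equation for a victim with CYP3A4 contribution `fm` and
#' baseline intestinal availability `fg`:
#' \deqn{AUCR = \frac{1}{(A_g B_g C_g)(1 - f_g) + f_g} \times
#'              \frac{1}{(A_h B_h C_h) f_m + (1 - f_m)}}
#' with the induction term `C = 1 + d * emax * I / (I + ec50)` evaluated at
#' the gut (`i_gut`) and unbound hepatic inlet (`i_h`) concentrations, and
#' reversible-inhibition (A) and inactivation (B) multipliers fixed at 1 for
#' a pure inducer. The gut factor is exactly the induced-availability factor
#' `fg'/fg` of the dynamic model evaluated at enzyme fold `Cg`.
#'
#' @param fm Victim fraction metabolized by CYP3A4, `[0, 1]`.
#' @param fg Victim baseline intestinal availability, `(0, 1]`.
#' @param i_gut Intestinal perpetrator concentration (uM).
#' @param i_h Unbound hepatic inlet perpetrator concentration (uM).
#' @param induction Perpetrator induction parameters (`ec50`, `emax`).
#' @param d_factor Induction scaling factor d (guidance default 1).
#' @param a_gut,b_gut,a_hep,b_hep Inhibition multipliers (default 1).
#' @return Predicted AUCR (with A = B = 1 and induction only, in `(0, 1]`).
#' @examples
#' ind <- rifampicin_model()$induction
#' static_aucr(fm = 1, fg = 1, i_gut = 0, i_h = 1e6, induction = ind)
#' # -> 1/(1 + 14.6)
#' @export
static_aucr <- function(fm, fg, i_gut, i_h, induction, d_factor = 1,
                        a_gut = 1, b_gut = 1, a_hep = 1, b_hep = 1) {
  stopifnot(fm >= 0, fm <= 1, fg > 0, fg <= 1, i_gut >= 0, i_h >= 0,
            d_factor >= 0)
  cg <- 1 + d_factor * induction$emax * i_gut / (i_gut + induction$ec50)
  ch <- 1 + d_factor * induction$emax * i_h / (i_h + induction$ec50)
  gut_term <- 1 / ((a_gut * b_gut * cg) * (1 - fg) + fg)
  hep_term <- 1 / ((a_hep * b_hep * ch) * fm + (1 - fm))
  gut_term * hep_term
}

#' Default rifampicin inputs for the static model
#'
#' Assembles the perpetrator-side static-model inputs for 600 mg rifampicin:
#' `i_gut` from the 250 mL convention and `i_h` from the steady-state Cmax —
#' either simulated (7-day once-daily run with autoinduction, the default)
#' or the packaged observed-study predicted value (`cmax_ss` supplied
#' directly, e.g. 11.2 mg/L from the day-6 once-daily validation row).
#' `Fa` and `ka` come from the absorption submodel.
#'
#' @param perpetrator Perpetrator [drug_model()] (default rifampicin).
#' @param phys A [default_physiology()].
#' @param dose Perpetrator dose (mg).
#' @param cmax_ss Steady-state Cmax (mg/L); if `NULL`, simulated.
#' @return List with `i_gut`, `i_h`, `cmax_ss`, `fa`, `ka`, `induction`.
#' @export
rifampicin_static_inputs <- function(perpetrator = rifampicin_model(),
                                     phys = default_physiology(),
                                     dose = 600, cmax_ss = NULL) {
  ap <- absorption_params(perpetrator$compound, phys)
  if (is.null(cmax_ss)) {
    prof <- simulate_pk(perpetrator,
                        dose_regimen("oral", dose, n_doses = 7, interval = 24),
                        phys, t_end = 7 * 24, dt_out = 0.1,
                        autoinduction = TRUE)
    day7 <- clip_profile(prof, 6 * 24, 7 * 24)
    cmax_ss <- max(day7$conc)
  }
  list(
    i_gut = gut_concentration(dose, perpetrator$compound$molecular_weight),
    i_h = hepatic_inlet_unbound(cmax_ss, dose, fa = ap$fa_closed_form,
                                fg = perpetrator$clearance$fg, ka = ap$ka,
                                qh = phys$hepatic_blood_flow_qh,
                                rbp = perpetrator$compound$rbp,
                                fup = perpetrator$compound$fup,
                                mw = perpetrator$compound$molecular_weight),
    cmax_ss = cmax_ss, fa = ap$fa_closed_form, ka = ap$ka,
    induction = perpetrator$induction
  )
}

#' Invert the static model for fm
#'
#' Recovers the victim `fm` that reproduces a target static AUCR, by
#' bisection on the monotone hepatic term (fg and the perpetrator inputs
#' held fixed). Returns `NA` when the target is outside the attainable
#' range.
#'
#' @param target_aucr Target AUCR, > 0.
#' @inheritParams static_aucr
#' @return `fm` in `[0, 1]`, or `NA`.
#' @export
static_fm_from_aucr <- function(target_aucr, fg, i_gut, i_h, induction,
                                d_factor = 1) {
  f <- function(fm) static_aucr(fm, fg, i_gut, i_h, induction, d_factor) -
    target_aucr
  lo <- f(1); hi <- f(0)
  if (lo > 0 || hi < 0) return(NA_real_)
  uniroot(f, c(0, 1), tol = 1e-10)$root
}

#' Static predictions alongside the packaged panel
#'
#' Computes static-model AUCR predictions for supplied victim `fm`/`fg`
#' values and lines them up with the published static column of the
#' interaction table, for qualitative comparison (the panel's own victim
#' parameters are not published, so no per-drug agreement is implied).
#'
#' @param records The interaction table ([load_ddi_table()]) or a subset.
#' @param victims Data.frame with columns `fm` and `fg`, one row per record
#'   (or a single row recycled).
#' @param inputs Static inputs as from [rifampicin_static_inputs()].
#' @return Data.frame: `victim`, `fm`, `fg`, `static_aucr`,
#'   `published_static_aucr`, `observed_aucr`.
#' @export
static_vs_table <- function(records, victims,
                            inputs = rifampicin_static_inputs(cmax_ss = 11.2)) {
  if (nrow(records) == 0L) {
    return(data.frame(victim = character(0), fm = numeric(0), fg = numeric(0),
                      static_aucr = numeric(0),
                      published_static_aucr = numeric(0),
                      observed_aucr = numeric(0)))
  }
  if (nrow(victims) == 1L) victims <- victims[rep(1L, nrow(records)), ]
  stopifnot(nrow(victims) == nrow(records))
  pred <- mapply(function(fm, fg) {
    static_aucr(fm, fg, inputs$i_gut, inputs$i_h, inputs$induction)
  }, victims$fm, victims$fg)
  data.frame(victim = records$victim, fm = victims$fm, fg = victims$fg,
             static_aucr = pred,
             published_static_aucr = records$predicted_aucr_static,
             observed_aucr = records$observed_aucr)
}
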