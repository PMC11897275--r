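# ODE engine: transit-chain oral absorption + 1-3 compartment disposition +
# clearance partition (CYP3A4 / other hepatic / renal), optionally coupled to
# the CYP3A4 turnover model. One generic right-hand side serves single-drug
# simulations and victim/perpetrator co-simulations; per-kg parameters are
# scaled by body weight here, at build time.

#' Transit-chain absorption parameters
#'
#' Derives the first-order rates of the compartmental absorption-transit
#' model: transit rate `kt = n / small_intestine_transit_time` and absorption
#' rate `ka = 2 * Peff / intestine_radius` (converted from cm/s to 1/h), the
#' cylindrical-lumen relation between effective permeability and absorption.
#' The closed-form fraction absorbed of the pure first-order chain,
#' `Fa = 1 - (kt / (kt + ka))^n`, is returned for reference.
#'
#' @param compound Compound property list (uses `peff`, in 1e-4 cm/s).
#' @param phys A [default_physiology()] object.
#' @return List with `ka` (1/h), `kt` (1/h), `n`, and `fa_closed_form`.
#' @examples
#' absorption_params(rifampicin_model()$compound, default_physiology())
#' @export
absorption_params <- function(compound, phys) {
  stopifnot(compound$peff >= 0)
  ka <- 2 * compound$peff * 1e-4 / phys$intestine_radius * 3600
  kt <- phys$n_gut_compartments / phys$small_intestine_transit_time
  fa <- if (ka == 0) 0 else 1 - (kt / (kt + ka))^phys$n_gut_compartments
  list(ka = ka, kt = kt, n = phys$n_gut_compartments, fa_closed_form = fa)
}

# First-order dissolution rate (1/h) from a Noyes-Whitney-style film model:
# kdiss = 3 D Cs / (rho r^2). Diffusion coefficient 5e-6 cm2/s, true density
# 1.2 g/cm3. Only used when dissolution is enabled.
dissolution_rate <- function(compound) {
  cs <- compound$aqueous_solubility # mg/mL = mg/cm3
  if (is.null(cs) || cs <= 0) return(0)
  r_cm <- compound$particle_radius * 1e-4
  3 * 5e-6 * cs / (1200 * r_cm^2) * 3600
}

# Compile one drug + regimen into an index layout and scaled parameters.
compile_drug <- function(drug, regimen, phys, offset, dissolution = FALSE) {
  dp <- drug$disposition
  cl <- drug$clearance
  bw <- phys$body_weight
  abs_par <- absorption_params(drug$compound, phys)
  oral <- regimen$route == "oral"
  n_gut <- phys$n_gut_compartments

  nm <- character(0)
  if (oral) {
    nm <- c(nm, paste0("gut", seq_len(n_gut)))
    if (dissolution) nm <- c(nm, paste0("solid", seq_len(n_gut)))
  }
  nm <- c(nm, "central")
  has_p1 <- dp$k12 > 0 || dp$k21 > 0
  has_p2 <- !is.null(dp$k13)
  if (has_p1) nm <- c(nm, "p1")
  if (has_p2) nm <- c(nm, "p2")
  # gut-wall extraction is ledgered separately from hepatic CYP3A4
  # metabolism so the realized intestinal availability can be read back
  nm <- c(nm, "met_cyp", "met_other", "renal", "unabsorbed", "gut_ext")

  idx <- setNames(offset + seq_along(nm), nm)
  list(
    name = drug$name,
    oral = oral,
    n_gut = n_gut,
    dissolution = dissolution && oral,
    kdiss = dissolution_rate(drug$compound),
    idx = idx,
    state_names = nm,
    i_gut = if (oral) unname(idx[paste0("gut", seq_len(n_gut))]) else integer(0),
    i_solid = if (oral && dissolution)
      unname(idx[paste0("solid", seq_len(n_gut))]) else integer(0),
    i_central = unname(idx[["central"]]),
    i_p1 = if (has_p1) unname(idx[["p1"]]) else NA_integer_,
    i_p2 = if (has_p2) unname(idx[["p2"]]) else NA_integer_,
    i_cum = unname(idx[c("met_cyp", "met_other", "renal", "unabsorbed",
                         "gut_ext")]),
    vc_tot = dp$vc * bw,
    k12 = dp$k12, k21 = dp$k21,
    k13 = if (has_p2) dp$k13 else 0, k31 = if (has_p2) dp$k31 else 0,
    cl_cyp = cl$cl_cyp3a4_hepatic * bw,
    cl_other = cl$cl_other_hepatic * bw,
    cl_renal = cl$cl_renal * bw,
    mm = identical(cl$vmax_mode, "michaelis_menten"),
    km = if (!is.null(cl$km)) cl$km else NA_real_,
    # Vmax calibrated so sub-Km clearance equals the baseline linear CL
    vmax = if (identical(cl$vmax_mode, "michaelis_menten"))
      cl$cl_cyp3a4_hepatic * bw * cl$km else NA_real_,
    fg = cl$fg,
    ka = abs_par$ka, kt = abs_par$kt,
    mw = drug$compound$molecular_weight,
    fup = drug$compound$fup,
    regimen = regimen,
    affected = FALSE # CYP3A4 clearance scales with the enzyme state?
  )
}

# Build the full ODE system for one or more drugs sharing one CYP3A4 pool.
# `drugs` is a named list of list(drug=, regimen=). The first drug carrying
# an induction block is the inducer; enzyme states are appended when an
# inducer is present and induction is active. `autoinduction` couples the
# inducer's own CYP3A4 pathway to the enzyme state.
make_system <- function(drugs, phys, induction_active = TRUE,
                        autoinduction = FALSE, dissolution = FALSE) {
  stopifnot(length(drugs) >= 1L)
  compiled <- list()
  offset <- 0L
  inducer_key <- NULL
  for (key in names(drugs)) {
    d <- drugs[[key]]
    compiled[[key]] <- compile_drug(d$drug, d$regimen, phys, offset,
                                    dissolution = dissolution)
    offset <- offset + length(compiled[[key]]$state_names)
    if (is.null(inducer_key) && !is.null(d$drug$induction)) inducer_key <- key
  }
  induction <- if (!is.null(inducer_key)) drugs[[inducer_key]]$drug$induction
  has_enzyme <- induction_active && !is.null(induction)

  n_gut <- phys$n_gut_compartments
  i_e_liver <- i_e_gut <- NULL
  enzyme_names <- character(0)
  if (has_enzyme) {
    enzyme_names <- c("e_liver", paste0("e_gut", seq_len(n_gut)))
    i_e_liver <- offset + 1L
    i_e_gut <- offset + 1L + seq_len(n_gut)
    offset <- offset + 1L + n_gut
    for (key in names(compiled)) {
      compiled[[key]]$affected <-
        has_enzyme && (key != inducer_key || autoinduction)
    }
  }

  state_names <- c(unlist(lapply(names(compiled), function(k) {
    paste0(k, ".", compiled[[k]]$state_names)
  }), use.names = FALSE), enzyme_names)
  y0 <- setNames(numeric(length(state_names)), state_names)
  if (has_enzyme) y0[c(i_e_liver, i_e_gut)] <- 1

  # dose events and infusion windows
  ev <- list(); inf_windows <- list()
  for (k in names(compiled)) {
    cd <- compiled[[k]]
    reg <- cd$regimen
    tdose <- regimen_dose_times(reg)
    if (reg$route == "oral") {
      target <- if (cd$dissolution) cd$i_solid[1] else cd$i_gut[1]
      ev[[k]] <- data.frame(var = state_names[target], time = tdose,
                            value = reg$dose, method = "add")
    } else if (reg$route == "iv_bolus") {
      ev[[k]] <- data.frame(var = state_names[cd$i_central], time = tdose,
                            value = reg$dose, method = "add")
    } else { # infusion: zero-add events force solver restarts at the kinks
      inf_windows[[k]] <- cbind(start = tdose,
                                end = tdose + reg$infusion_duration,
                                rate = reg$dose / reg$infusion_duration)
      ev[[k]] <- data.frame(var = state_names[cd$i_central],
                            time = sort(c(tdose, tdose + reg$infusion_duration)),
                            value = 0, method = "add")
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time), , drop = FALSE]
  # doses at t = 0 go into the initial state; an event there would only be
  # applied after the first output row
  at0 <- events$time <= 0
  if (any(at0)) {
    for (j in which(at0)) {
      y0[events$var[j]] <- y0[events$var[j]] + events$value[j]
    }
    events <- events[!at0, , drop = FALSE]
  }

  qent <- phys$enterocyte_blood_flow_qent
  ind_drv <- if (has_enzyme) compiled[[inducer_key]]

  rhs <- function(t, y, parms) {
    dy <- numeric(length(y))

    e_liver <- if (has_enzyme) y[i_e_liver] else 1
    e_gut <- if (has_enzyme) y[i_e_gut] else rep(1, n_gut)

    if (has_enzyme) {
      cu_liver <- ind_drv$fup * (y[ind_drv$i_central] / ind_drv$vc_tot) /
        ind_drv$mw * 1000
      cu_gut <- if (ind_drv$oral) {
        ind_drv$ka * y[ind_drv$i_gut] / qent / ind_drv$mw * 1000
      } else rep(0, n_gut)
      cu_liver <- max(cu_liver, 0); cu_gut <- pmax(cu_gut, 0)
      fold_l <- 1 + induction$emax * cu_liver / (induction$ec50 + cu_liver)
      fold_g <- 1 + induction$emax * cu_gut / (induction$ec50 + cu_gut)
      dy[i_e_liver] <- induction$kdeg_liver * (fold_l - e_liver)
      dy[i_e_gut] <- induction$kdeg_gut * (fold_g - e_gut)
    }

    for (cd in compiled) {
      el <- if (cd$affected) e_liver else 1
      into_central <- 0; gut_met <- 0; unabs <- 0
      if (cd$oral) {
        g <- y[cd$i_gut]
        if (cd$dissolution) {
          s <- y[cd$i_solid]
          diss <- cd$kdiss * s
          ds <- -(cd$kt * s) - diss
          if (cd$n_gut > 1L) ds[-1] <- ds[-1] + cd$kt * s[-cd$n_gut]
          dy[cd$i_solid] <- ds
          unabs <- unabs + cd$kt * s[cd$n_gut]
        } else diss <- 0
        absorbed <- cd$ka * g
        eg <- if (cd$affected) e_gut else rep(1, cd$n_gut)
        fg_inst <- cd$fg / (cd$fg + (1 - cd$fg) * eg)
        dg <- -(cd$kt + cd$ka) * g + diss
        if (cd$n_gut > 1L) dg[-1] <- dg[-1] + cd$kt * g[-cd$n_gut]
        dy[cd$i_gut] <- dg
        into_central <- sum(absorbed * fg_inst)
        gut_met <- sum(absorbed * (1 - fg_inst))
        unabs <- unabs + cd$kt * g[cd$n_gut]
      }
      inf_rate <- 0
      w <- inf_windows[[cd$name]]
      if (!is.null(w)) {
        act <- t >= w[, "start"] & t < w[, "end"]
        if (any(act)) inf_rate <- sum(w[act, "rate"])
      }
      conc <- y[cd$i_central] / cd$vc_tot
      met_cyp <- if (cd$mm) {
        el * cd$vmax * conc / (cd$km + conc)
      } else el * cd$cl_cyp * conc
      met_other <- cd$cl_other * conc
      ren <- cd$cl_renal * conc
      dc <- into_central + inf_rate - (met_cyp + met_other + ren)
      if (!is.na(cd$i_p1)) {
        dc <- dc + cd$k21 * y[cd$i_p1] - cd$k12 * y[cd$i_central]
        dy[cd$i_p1] <- cd$k12 * y[cd$i_central] - cd$k21 * y[cd$i_p1]
      }
      if (!is.na(cd$i_p2)) {
        dc <- dc + cd$k31 * y[cd$i_p2] - cd$k13 * y[cd$i_central]
        dy[cd$i_p2] <- cd$k13 * y[cd$i_central] - cd$k31 * y[cd$i_p2]
      }
      dy[cd$i_central] <- dc
      dy[cd$i_cum] <- c(met_cyp, met_other, ren, unabs, gut_met)
    }
    list(dy)
  }

  # infusion windows are keyed by drug name for rhs lookup
  names(inf_windows) <- vapply(compiled[names(inf_windows)], `[[`, "", "name")

  list(compiled = compiled, rhs = rhs, y0 = y0, events = events,
       state_names = state_names, inducer_key = inducer_key,
       has_enzyme = has_enzyme, i_e_liver = i_e_liver, i_e_gut = i_e_gut,
       phys = phys)
}

# Integrate a compiled system. Returns the deSolve matrix plus layout.
integrate_system <- function(sys, t_end, dt_out = 0.05,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(dt_out > 0)
  tcrit <- unique(sort(c(sys$events$time)))
  if (length(tcrit) && max(tcrit) > t_end) {
    stop("t_end must cover all dose events", call. = FALSE)
  }
  times <- sort(unique(c(seq(0, t_end, by = dt_out), t_end, tcrit)))
  ev <- if (nrow(sys$events)) list(data = sys$events) else NULL
  out <- deSolve::lsoda(sys$y0, times, sys$rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000,
                        events = ev)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE solver failed to converge; see diagnostics via diagnostics()",
         call. = FALSE)
  }
  neg <- min(out[, -1L, drop = FALSE])
  if (neg < -1e-6 * max(abs(out[, -1L]))) {
    stop(sprintf("negative state beyond tolerance (min %g)", neg),
         call. = FALSE)
  }
  out
}

# Cumulative administered dose at each output time (infusions accrue).
cumulative_dosed <- function(regimen, times) {
  dosed <- numeric(length(times))
  for (td in regimen_dose_times(regimen)) {
    if (regimen$route == "iv_infusion") {
      dur <- regimen$infusion_duration
      dosed <- dosed + regimen$dose * pmin(pmax(times - td, 0), dur) / dur
    } else if (td <= 0) {
      # time-zero doses sit in the initial state
      dosed <- dosed + regimen$dose
    } else {
      # later bolus doses are solver events; the output row at the event
      # time itself is pre-event
      dosed <- dosed + regimen$dose * (times > td)
    }
  }
  dosed
}

# Extract one drug's conc_profile (with bookkeeping) from an integration.
extract_profile <- function(sys, out, key) {
  cd <- sys$compiled[[key]]
  times <- out[, "time"]
  conc <- out[, cd$i_central + 1L] / cd$vc_tot
  body_idx <- c(cd$i_gut, cd$i_solid, cd$i_central,
                cd$i_p1[!is.na(cd$i_p1)], cd$i_p2[!is.na(cd$i_p2)])
  in_body <- rowSums(out[, body_idx + 1L, drop = FALSE])
  elim <- as.data.frame(out[, cd$i_cum[1:4] + 1L, drop = FALSE])
  names(elim) <- c("metabolic_cyp3a4", "metabolic_other", "renal",
                   "unabsorbed")
  gut_ext <- out[, cd$i_cum[5] + 1L]
  # report CYP3A4 elimination as gut + liver in the public ledger
  elim$metabolic_cyp3a4 <- elim$metabolic_cyp3a4 + gut_ext
  reg <- cd$regimen
  dose_events <- data.frame(time = regimen_dose_times(reg),
                            amount = reg$dose, route = reg$route)
  prof <- conc_profile(times = times, conc = conc, dose_events = dose_events,
                       eliminated = elim, in_body = in_body,
                       dosed = cumulative_dosed(reg, times))
  prof$route <- reg$route
  prof$dose_total <- reg$dose * reg$n_doses
  prof$gut_extracted <- gut_ext
  if (sys$has_enzyme) {
    prof$enzyme <- data.frame(time = times,
                              e_rel_liver = out[, sys$i_e_liver + 1L],
                              e_rel_gut = rowMeans(out[, sys$i_e_gut + 1L,
                                                       drop = FALSE]))
  }
  prof
}

#' Simulate a plasma concentration-time profile
#'
#' Integrates the compartmental model of one drug under a dosing regimen:
#' serial gut transit compartments with first-order absorption (oral), 1-3
#' disposition compartments, and the three-way clearance partition
#' (CYP3A4-mediated hepatic, other hepatic, renal). For an inducer dosed to
#' multiplicity, `autoinduction = TRUE` couples its own CYP3A4 pathway to the
#' enzyme-turnover model so that clearance rises over repeated doses.
#'
#' Solver: `deSolve::lsoda`, rtol 1e-8 / atol 1e-10 by default; dose events
#' are handled as integration restarts. Every simulation carries a full mass
#' ledger (amount in body, cumulative elimination per route, unabsorbed) so
#' that mass balance can be verified at every output point.
#'
#' @param drug A [drug_model()].
#' @param regimen A [dose_regimen()].
#' @param phys A [default_physiology()].
#' @param t_end End of simulation (h); default last dose + 48 h.
#' @param dt_out Output grid step (h), default 0.05.
#' @param autoinduction Couple the drug's own CYP3A4 clearance to its induced
#'   enzyme state (inducers only).
#' @param dissolution Enable the first-order dissolution limitation (off by
#'   default; rifampicin's 1.1 mg/mL solubility is non-limiting at the doses
#'   simulated here).
#' @param rtol,atol Solver tolerances.
#' @return A [conc_profile()]; when enzyme dynamics are active it carries an
#'   `enzyme` data.frame (`time`, `e_rel_liver`, `e_rel_gut`).
#' @examples
#' \donttest{
#' rif <- rifampicin_model()
#' prof <- simulate_pk(rif, dose_regimen("iv_infusion", 600,
#'                                       infusion_duration = 1), t_end = 24)
#' max(prof$conc)
#' }
#' @export
simulate_pk <- function(drug, regimen, phys = default_physiology(),
                        t_end = NULL, dt_out = 0.05, autoinduction = FALSE,
                        dissolution = FALSE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(drug, "drug_model"), inherits(regimen, "dose_regimen"))
  if (is.null(t_end)) t_end <- max(regimen_dose_times(regimen)) + 48
  sys <- make_system(list(drug = list(drug = drug, regimen = regimen)),
                     phys, induction_active = autoinduction,
                     autoinduction = autoinduction, dissolution = dissolution)
  out <- integrate_system(sys, t_end, dt_out, rtol, atol)
  extract_profile(sys, out, "drug")
}

#' Worst-case relative mass-balance error of a simulation
#'
#' At every output time compares the cumulative administered dose against
#' amount-in-body + cumulative eliminated + unabsorbed, relative to total
#' administered dose.
#'
#' @param profile A simulated [conc_profile()].
#' @return Maximum relative mass-balance error (fraction of total dose).
#' @export
mass_balance_error <- function(profile) {
  if (is.null(profile$eliminated) || is.null(profile$dosed)) {
    stop("profile carries no mass ledger (was it read from CSV?)",
         call. = FALSE)
  }
  accounted <- profile$in_body + rowSums(profile$eliminated)
  ref <- max(profile$dosed)
  if (ref == 0) return(max(abs(accounted)))
  max(abs(profile$dosed - accounted)) / ref
}

#' Fraction of an oral dose absorbed from the gut lumen
#'
#' `Fa = 1 - unabsorbed / dose`, from the simulation's unabsorbed
#' bookkeeping at the final output time. Absorption into the gut wall counts
#' as absorbed even if subsequently extracted there.
#'
#' @param profile A simulated oral [conc_profile()].
#' @return Fraction absorbed in `[0, 1]`.
#' @export
fraction_absorbed <- function(profile) {
  if (is.null(profile$route) || profile$route != "oral") {
    stop("fraction_absorbed requires an oral simulation", call. = FALSE)
  }
  unabs <- tail(profile$eliminated$unabsorbed, 1L)
  fa <- 1 - unabs / profile$dose_total
  min(max(fa, 0), 1)
}

#' Closed-form two-compartment IV-bolus profile
#'
#' Bi-exponential analytic solution used as the independent oracle for the
#' ODE engine. Macro-constants are derived from `k10 = CL/(Vc*BW)`, `k12`,
#' `k21`: `alpha + beta = k10 + k12 + k21`, `alpha*beta = k10*k21`. With
#' `k12 = k21 = 0` it degenerates to the mono-exponential one-compartment
#' solution, and for any rate constants `AUC(0-inf) = dose/CL`.
#'
#' @param disposition Disposition list (`vc`, `k12`, `k21`; no third
#'   compartment).
#' @param cl_total Total linear plasma clearance (L/h, absolute).
#' @param dose IV bolus dose (mg).
#' @param bw Body weight (kg).
#' @param times Output times (h).
#' @return A [conc_profile()].
#' @export
analytic_two_compartment_iv <- function(disposition, cl_total, dose, bw,
                                        times) {
  if (!is.null(disposition$k13)) {
    stop("analytic oracle is limited to two compartments", call. = FALSE)
  }
  vc_tot <- disposition$vc * bw
  k10 <- cl_total / vc_tot
  k12 <- disposition$k12
  k21 <- disposition$k21
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- dose / vc_tot
  conc <- if (alpha == beta) {
    c0 * exp(-alpha * times)
  } else {
    a_coef <- c0 * (alpha - k21) / (alpha - beta)
    b_coef <- c0 * (k21 - beta) / (alpha - beta)
    a_coef * exp(-alpha * times) + b_coef * exp(-beta * times)
  }
  prof <- conc_profile(times, conc,
                       dose_events = data.frame(time = times[1], amount = dose,
                                                route = "iv_bolus"))
  prof$route <- "iv_bolus"
  prof$dose_total <- dose
  prof
}
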