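#' Define a dosing regimen
#'
#' @param route One of `"iv_bolus"`, `"iv_infusion"`, `"oral"`.
#' @param dose Dose per administration (mg), > 0.
#' @param n_doses Number of administrations (>= 1).
#' @param interval Dosing interval (h); required when `n_doses > 1`.
#' @param infusion_duration Infusion duration (h); IV infusion only.
#' @param start_time Time of the first dose (h).
#'
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen("oral", 600, n_doses = 7, interval = 24)
#' @export
dose_regimen <- function(route = c("oral", "iv_bolus", "iv_infusion"),
                         dose, n_doses = 1L, interval = 24,
                         infusion_duration = NULL, start_time = 0) {
  route <- match.arg(route)
  if (!is.numeric(dose) || dose <= 0) stop("dose must be > 0", call. = FALSE)
  n_doses <- as.integer(n_doses)
  if (n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  if (n_doses > 1L && (!is.numeric(interval) || interval <= 0)) {
    stop("interval must be > 0 when n_doses > 1", call. = FALSE)
  }
  if (route == "iv_infusion") {
    if (is.null(infusion_duration) || infusion_duration <= 0) {
      stop("iv_infusion requires infusion_duration > 0", call. = FALSE)
    }
  } else {
    infusion_duration <- NULL
  }
  structure(list(route = route, dose = dose, n_doses = n_doses,
                 interval = interval, infusion_duration = infusion_duration,
                 start_time = start_time),
            class = "dose_regimen")
}

regimen_dose_times <- function(reg) {
  reg$start_time + (seq_len(reg$n_doses) - 1L) * reg$interval
}

#' @export
print.dose_regimen <- function(x, ...) {
  extra <- if (x$route == "iv_infusion") {
    sprintf(" over %g h", x$infusion_duration)
  } else ""
  cat(sprintf("<dose_regimen> %g mg %s%s x%d%s, first dose at t = %g h\n",
              x$dose, x$route, extra, x$n_doses,
              if (x$n_doses > 1L) sprintf(" q%gh", x$interval) else "",
              x$start_time))
  invisible(x)
}

#' Build a concentration-time profile object
#'
#' Container for a central-compartment plasma concentration trajectory plus
#' the dose bookkeeping the downstream stages (NCA, DDI ratios, mass-balance
#' checks, fraction absorbed) need. Simulation output carries the full
#' elimination ledger; profiles read back from CSV carry concentrations only.
#'
#' @param times Strictly increasing time grid (h).
#' @param conc Plasma concentrations (mg/L), same length as `times`.
#' @param dose_events Optional data.frame with columns `time`, `amount`,
#'   `route`.
#' @param eliminated Optional data.frame (one row per output time) with
#'   cumulative amounts (mg) in columns `metabolic_cyp3a4`,
#'   `metabolic_other`, `renal`, `unabsorbed`.
#' @param in_body Optional numeric vector of total amount in the body (mg) at
#'   each output time.
#' @param dosed Optional numeric vector of cumulative administered dose (mg)
#'   at each output time (infusions accrue gradually).
#'
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(times, conc, dose_events = NULL, eliminated = NULL,
                         in_body = NULL, dosed = NULL) {
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) == 0L) stop("empty profile", call. = FALSE)
  if (length(times) != length(conc)) {
    stop("times and concentrations must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < -1e-9)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  conc[conc < 0] <- 0
  structure(list(times = times, conc = conc, dose_events = dose_events,
                 eliminated = eliminated, in_body = in_body, dosed = dosed),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %d points over [%g, %g] h; Cmax %.4g mg/L\n",
              length(x$times), min(x$times), max(x$times), max(x$conc)))
  if (!is.null(x$dose_events) && nrow(x$dose_events) > 0L) {
    cat(sprintf("  doses: %d events, %g mg total\n", nrow(x$dose_events),
                sum(x$dose_events$amount)))
  }
  invisible(x)
}

#' Restrict a profile to a time window
#'
#' Subsets a profile to `[t0, t1]`, interpolating the endpoints onto the grid
#' if needed, optionally shifting the window start to time zero. Used for
#' per-day NCA of multiple-dose simulations and for victim-dose windows in
#' DDI runs.
#'
#' @param profile A [conc_profile()].
#' @param t0,t1 Window bounds (h) on the profile's time axis.
#' @param shift If `TRUE` (default), returned times start at 0.
#' @return A [conc_profile()] (concentration data only).
#' @export
clip_profile <- function(profile, t0, t1 = max(profile$times), shift = TRUE) {
  stopifnot(inherits(profile, "conc_profile"), t1 > t0)
  keep <- profile$times >= t0 & profile$times <= t1
  if (sum(keep) < 2L) stop("window contains fewer than 2 points", call. = FALSE)
  times <- profile$times[keep]
  conc <- profile$conc[keep]
  if (times[1] > t0) {
    c0 <- approx(profile$times, profile$conc, xout = t0)$y
    times <- c(t0, times); conc <- c(c0, conc)
  }
  if (shift) times <- times - t0
  conc_profile(times, conc)
}

#' Write / read a concentration-time profile as CSV
#'
#' Profiles are exchanged as two-column CSV (`time_h`, `conc_mg_per_L`),
#' dot-decimal, UTF-8, with 15 significant digits so that a write/read
#' round trip reproduces the profile to floating-point text precision.
#' Only the concentration trajectory is serialized.
#'
#' @param profile A [conc_profile()].
#' @param path Output/input CSV path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns a
#'   [conc_profile()].
#' @examples
#' p <- conc_profile(c(0, 1), c(0, 5))
#' f <- tempfile(fileext = ".csv")
#' write_profile(p, f)
#' identical(read_profile(f)$conc, p$conc)
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "conc_profile"))
  df <- data.frame(time_h = format(profile$times, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                   conc_mg_per_L = format(profile$conc, digits = 15,
                                          trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such profile: %s", path),
                               call. = FALSE)
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time_h", "conc_mg_per_L") %in% names(df))) {
    stop("profile CSV must have columns time_h, conc_mg_per_L", call. = FALSE)
  }
  conc_profile(df$time_h, df$conc_mg_per_L)
}
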