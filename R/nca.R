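#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes the standard NCA parameter set: Cmax, Tmax (earliest time on
#' ties), AUC to the last positive concentration by the linear-up/log-down
#' trapezoid rule (configurable to pure linear), the terminal slope lambda_z
#' by log-linear regression over an automatically selected terminal window
#' (all candidate windows of >= 3 points strictly after Tmax; the one
#' maximizing adjusted R-squared wins, with more points preferred on
#' near-ties), and the derived quantities T1/2 = ln 2 / lambda_z,
#' AUC(0-inf) = AUC(0-t) + Clast/lambda_z, CL/F = dose/AUC(0-inf) and
#' V/F = (CL/F)/lambda_z.
#'
#' Concentrations in mg/L are numerically identical to ug/mL, so AUCs are
#' reported in ug.h/mL without conversion.
#'
#' @param profile A [conc_profile()].
#' @param dose Administered dose (mg) for CL/F and V/F; optional.
#' @param method `"linear_log"` (linear-up/log-down, default) or `"linear"`.
#' @param min_terminal_points Minimum points in the lambda-z window.
#' @return An object of class `nca_result`: list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `t_half`, `cl_f`, `v_f`,
#'   `extrap_pct`, `lambda_z_n_points`, `lambda_z_adj_r2`,
#'   `lambda_z_estimable`.
#' @examples
#' tt <- seq(0, 24, 0.05)
#' p <- conc_profile(tt, 10 * exp(-0.5 * tt))
#' run_nca(p, dose = 100)$auc_inf # ~20
#' @export
run_nca <- function(profile, dose = NULL,
                    method = c("linear_log", "linear"),
                    min_terminal_points = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_profile"))
  tt <- profile$times
  cc <- profile$conc
  if (sum(cc > 0) < 3L) {
    stop("NCA requires at least 3 positive concentrations", call. = FALSE)
  }
  imax <- which.max(cc) # which.max returns the first maximum: earliest Tmax
  cmax <- cc[imax]
  tmax <- tt[imax]

  ilast <- max(which(cc > 0))
  auc_last <- auc_trapezoid(tt[1:ilast], cc[1:ilast], method)

  # terminal window: points strictly after tmax with positive concentration
  cand <- which(tt > tmax & cc > 0)
  lz <- NULL
  if (length(cand) >= min_terminal_points) {
    fits <- lapply(seq(min_terminal_points, length(cand)), function(k) {
      idx <- tail(cand, k)
      x <- tt[idx]; y <- log(cc[idx])
      sxx <- sum((x - mean(x))^2)
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      syy <- sum((y - mean(y))^2)
      slope <- -sxy / sxx
      if (!is.finite(slope) || slope <= 0) return(NULL)
      r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
      list(lambda_z = slope, ar2 = 1 - (1 - r2) * (k - 1) / (k - 2), n = k)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) {
      # best adjusted R2; on near-ties (within 1e-4) prefer more points
      ar2s <- vapply(fits, `[[`, numeric(1), "ar2")
      ok <- which(ar2s >= max(ar2s) - 1e-4)
      lz <- fits[[ok[length(ok)]]]
    }
  }

  res <- list(cmax = cmax, tmax = tmax, auc_last = auc_last,
              auc_inf = NA_real_, lambda_z = NA_real_, t_half = NA_real_,
              cl_f = NA_real_, v_f = NA_real_, extrap_pct = NA_real_,
              lambda_z_n_points = NA_integer_, lambda_z_adj_r2 = NA_real_,
              lambda_z_estimable = !is.null(lz))
  if (!is.null(lz)) {
    clast <- cc[ilast]
    res$lambda_z <- lz$lambda_z
    res$t_half <- log(2) / lz$lambda_z
    res$auc_inf <- auc_last + clast / lz$lambda_z
    res$extrap_pct <- 100 * (res$auc_inf - auc_last) / res$auc_inf
    res$lambda_z_n_points <- lz$n
    res$lambda_z_adj_r2 <- lz$ar2
    if (!is.null(dose)) {
      res$cl_f <- dose / res$auc_inf
      res$v_f <- res$cl_f / lz$lambda_z
    }
  }
  structure(res, class = "nca_result")
}

# trapezoid AUC; linear on rising/equal segments, log on falling segments
auc_trapezoid <- function(tt, cc, method = "linear_log") {
  dt <- diff(tt)
  c1 <- head(cc, -1L)
  c2 <- tail(cc, -1L)
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear_log") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
      log(c1[logdown] / c2[logdown])
  }
  sum(seg)
}

#' AUC of a profile over a time window
#'
#' Convenience wrapper around the NCA trapezoid rule for interval AUCs
#' (e.g. a steady-state dosing interval).
#'
#' @param profile A [conc_profile()].
#' @param t0,t1 Window bounds (h); default full profile.
#' @param method Trapezoid variant, as in [run_nca()].
#' @return AUC over the window (ug.h/mL).
#' @export
auc_interval <- function(profile, t0 = min(profile$times),
                         t1 = max(profile$times), method = "linear_log") {
  w <- clip_profile(profile, t0, t1, shift = FALSE)
  auc_trapezoid(w$times, w$conc, method)
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  cat(sprintf("  Cmax %.4g ug/mL at Tmax %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC(0-t) %.5g, AUC(0-inf) %.5g ug.h/mL (%.2f%% extrapolated)\n",
              x$auc_last, x$auc_inf, x$extrap_pct))
  cat(sprintf("  lambda_z %.4g 1/h (T1/2 %.3g h, %d points, adj R2 %.4f)\n",
              x$lambda_z, x$t_half, x$lambda_z_n_points, x$lambda_z_adj_r2))
  if (is.finite(x$cl_f)) {
    cat(sprintf("  CL/F %.4g L/h, V/F %.4g L\n", x$cl_f, x$v_f))
  }
  invisible(x)
}

#' Percent prediction error
#'
#' `100 * (predicted - observed) / observed`, rounded to two decimals — the
#' reporting convention of the packaged rifampicin validation table (whose IV
#' rows define the sign convention).
#'
#' @param predicted,observed Positive values in the same units;
#'   `observed != 0`.
#' @return Signed percent error, rounded to 2 decimals.
#' @examples
#' percent_error(31.9, 37.6) # -15.16
#' @export
percent_error <- function(predicted, observed) {
  if (any(observed == 0)) stop("observed must be non-zero", call. = FALSE)
  round(100 * (predicted - observed) / observed, 2)
}
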