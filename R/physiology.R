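#' Reference adult physiology
#'
#' Returns the physiological constants the simulation and the static model
#' need: body weight, hepatic and enterocyte blood flows, glomerular
#' filtration rate, and the geometry of the small-intestinal transit chain.
#' Values are standard adult defaults used across PBPK platforms; all are
#' overridable.
#'
#' @param body_weight Subject body weight (kg).
#' @param hepatic_blood_flow_qh Hepatic blood flow Qh (L/h).
#' @param enterocyte_blood_flow_qent Enterocyte villous blood flow Qent (L/h),
#'   the drain used as the surrogate driver of gut-wall inducer exposure.
#' @param gfr Glomerular filtration rate (L/h).
#' @param n_gut_compartments Number of serial small-intestinal transit
#'   compartments.
#' @param small_intestine_transit_time Mean small-intestinal transit time (h).
#' @param intestine_radius Effective small-intestinal radius (cm), used to
#'   turn effective permeability into a first-order absorption rate.
#'
#' @return An object of class `physiology` (a validated list).
#' @examples
#' phys <- default_physiology()
#' phys$gfr # 7.2 L/h
#' @export
default_physiology <- function(body_weight = 70,
                               hepatic_blood_flow_qh = 97,
                               enterocyte_blood_flow_qent = 18,
                               gfr = 7.2,
                               n_gut_compartments = 7,
                               small_intestine_transit_time = 3.32,
                               intestine_radius = 1.75) {
  phys <- list(
    body_weight = body_weight,
    hepatic_blood_flow_qh = hepatic_blood_flow_qh,
    enterocyte_blood_flow_qent = enterocyte_blood_flow_qent,
    gfr = gfr,
    n_gut_compartments = as.integer(n_gut_compartments),
    small_intestine_transit_time = small_intestine_transit_time,
    intestine_radius = intestine_radius
  )
  num <- vapply(phys, as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all physiology parameters must be positive and finite", call. = FALSE)
  }
  if (phys$n_gut_compartments < 1L) {
    stop("n_gut_compartments must be >= 1", call. = FALSE)
  }
  structure(phys, class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat("<physiology>\n")
  cat(sprintf("  body weight      : %g kg\n", x$body_weight))
  cat(sprintf("  Qh / Qent / GFR  : %g / %g / %g L/h\n",
              x$hepatic_blood_flow_qh, x$enterocyte_blood_flow_qent, x$gfr))
  cat(sprintf("  gut transit      : %d compartments over %g h (radius %g cm)\n",
              x$n_gut_compartments, x$small_intestine_transit_time,
              x$intestine_radius))
  invisible(x)
}
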