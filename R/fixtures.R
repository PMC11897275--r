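# Packaged observed/predicted tables for the rifampicin DDI panel.
# Checksums guard the fixtures against silent edits: the loaders refuse to
# return data whose bytes differ from the transcribed release state.
.fixture_md5 <- c(
  ddi_table.csv = "bf6f832daae6e6afd52b58f2b34a61f3",
  pk_validation.csv = "6e5dfb17e38b7471fc8ed774ada6c005"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "pbpkddi", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[file]]))) {
    stop(sprintf("fixture integrity error: %s has checksum %s (expected %s)",
                 file, sum, .fixture_md5[[file]]), call. = FALSE)
  }
  path
}

#' Observed and predicted AUC ratios for the 28-drug victim panel
#'
#' Returns the packaged interaction table: for each of 28 victim drugs
#' co-administered with rifampicin, the dosing method, the observed AUC ratio
#' (with/without rifampicin), the AUC ratios predicted by the mechanistic
#' static model and by the dynamic PBPK-DDI model, and the published
#' predicted/observed fold-ratio columns for both methods (kept verbatim;
#' they can differ from ratios recomputed from the rounded AUCR columns,
#' e.g. telaprevir 2.03 published vs 2.00 recomputed).
#'
#' 26 victims were studied as single oral doses ("SD"); macitentan and
#' vorapaxar were evaluated at steady state under once-daily dosing ("QD").
#'
#' @return A data.frame of 28 rows with columns `victim`, `dosing`,
#'   `observed_aucr`, `predicted_aucr_static`, `predicted_aucr_pbpk`,
#'   `printed_ratio_static`, `printed_ratio_pbpk`.
#' @examples
#' ddi <- load_ddi_table()
#' subset(ddi, victim == "Abiraterone")
#' @export
load_ddi_table <- function() {
  tab <- read.csv(fixture_path("ddi_table.csv"), stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 28L, all(tab$observed_aucr > 0),
            all(tab$predicted_aucr_static > 0),
            all(tab$predicted_aucr_pbpk > 0))
  tab
}

#' Predicted vs observed rifampicin PK parameters
#'
#' Returns the packaged validation table for the rifampicin model: predicted
#' and observed non-compartmental parameters (Cmax, Tmax, AUC, V or V/F,
#' CL or CL/F, T1/2) for a 600 mg IV dose, 200 and 400 mg single oral doses,
#' and two once-daily 600 mg oral studies (days 1/4/6 and 1/4/7), together
#' with the published percent-error column. Units are ug/mL for Cmax,
#' ug.h/mL for AUC, h for Tmax and T1/2, L for volumes and L/h for
#' clearances.
#'
#' The published percent-error column is internally inconsistent for the oral
#' regimens (several rows do not equal 100*(predicted-observed)/observed);
#' the IV rows define the sign convention and are the ones used as exact
#' arithmetic checks.
#'
#' @return A data.frame with columns `regimen_label`, `parameter`, `day`
#'   (NA for single-dose rows), `predicted`, `observed`, `printed_error_pct`.
#' @examples
#' pk <- load_pk_validation_table()
#' subset(pk, regimen_label == "600 mg IV SD" & parameter == "Cmax")
#' @export
load_pk_validation_table <- function() {
  tab <- read.csv(fixture_path("pk_validation.csv"), stringsAsFactors = FALSE)
  stopifnot(all(tab$predicted > 0), all(tab$observed > 0))
  tab
}
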