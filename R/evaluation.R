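#' Predicted/observed fold ratio
#'
#' @param predicted,observed Positive exposure ratios (e.g. AUCRs);
#'   `observed > 0`.
#' @return `predicted / observed` (vectorized).
#' @export
fold_ratio <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed must be > 0", call. = FALSE)
  predicted / observed
}

#' Two-fold acceptance criterion
#'
#' A prediction passes when the predicted/observed ratio lies within
#' `[0.5, 2]`. Bounds are closed by default (a ratio of exactly 2.00
#' passes); set `bounds_inclusive = FALSE` for the open interval.
#'
#' @param ratio Predicted/observed ratio(s), > 0.
#' @param bounds_inclusive Closed interval bounds (default `TRUE`).
#' @return Logical vector of passes.
#' @export
twofold_pass <- function(ratio, bounds_inclusive = TRUE) {
  stopifnot(all(ratio > 0))
  if (bounds_inclusive) ratio >= 0.5 & ratio <= 2 else ratio > 0.5 & ratio < 2
}

#' Guest acceptance limit
#'
#' The observed-ratio-dependent acceptance limit of the Guest approach:
#' with `R = max(observed, 1/observed)`, `L = (delta + 2*(R - 1)) / R`. A
#' prediction passes when predicted/observed lies in `[1/L, L]`. The limit
#' is symmetric in the observed ratio (`L(r) = L(1/r)`), equals `delta` at an
#' observed ratio of 1, and relaxes towards the two-fold limit as the
#' observed effect grows (`L -> 2` as `R -> Inf` at `delta = 1`), making the
#' criterion strictest where the interaction is weakest.
#'
#' @param observed_ratio Observed exposure ratio(s), > 0.
#' @param delta Variability allowance, >= 1 (default 1, the no-variability
#'   limit).
#' @return Limit(s) `L >= 1`.
#' @examples
#' guest_limit(0.42) # 1.580
#' @export
guest_limit <- function(observed_ratio, delta = 1) {
  stopifnot(all(observed_ratio > 0), delta >= 1)
  r <- pmax(observed_ratio, 1 / observed_ratio)
  (delta + 2 * (r - 1)) / r
}

#' @rdname guest_limit
#' @param predicted Predicted exposure ratio(s), > 0.
#' @param observed Observed exposure ratio(s), > 0.
#' @return `guest_pass`: logical vector — `predicted/observed` within
#'   `[1/L, L]`.
#' @export
guest_pass <- function(predicted, observed, delta = 1) {
  lim <- guest_limit(observed, delta)
  ratio <- fold_ratio(predicted, observed)
  ratio >= 1 / lim & ratio <= lim
}

#' Concordance summary over an interaction table
#'
#' Applies the configured acceptance criterion to each record of a
#' predicted-vs-observed AUCR table (as returned by [load_ddi_table()]) and
#' aggregates to a pass count and an integer-rounded percentage, the format
#' of the panel's published bottom rows.
#'
#' `ratio_source = "recomputed"` divides the predicted by the observed AUCR
#' columns and rounds the ratio to `digits` decimals (the published
#' precision) before applying the criterion; `"printed"` uses the published
#' fold-ratio column verbatim. The two differ for boundary records whose
#' published ratio was computed from unrounded AUCRs (telaprevir 2.03
#' printed vs 2.00 recomputed); the per-record flags report which records
#' flip between the two sources.
#'
#' @param records Data.frame with columns `victim`, `observed_aucr`, the
#'   predicted AUCR columns, and the printed ratio columns.
#' @param model_column `"pbpk"` or `"static"` — which prediction to assess.
#' @param criterion `"twofold"` or `"guest"`.
#' @param ratio_source `"recomputed"` (default) or `"printed"`.
#' @param delta Guest variability allowance (>= 1).
#' @param bounds_inclusive Closed two-fold bounds (default `TRUE`).
#' @param digits Rounding applied to recomputed ratios (default 2, the
#'   published precision).
#' @return An object of class `concordance_summary`: list with `n`,
#'   `n_pass`, `pct_pass` (= `round(100 * n_pass / n)`), and
#'   `per_record_flags` (data.frame with the ratio used, pass flag, and the
#'   pass flag under the alternative ratio source).
#' @examples
#' summarize_concordance(load_ddi_table(), "pbpk")$pct_pass # 89
#' @export
summarize_concordance <- function(records,
                                  model_column = c("pbpk", "static"),
                                  criterion = c("twofold", "guest"),
                                  ratio_source = c("recomputed", "printed"),
                                  delta = 1, bounds_inclusive = TRUE,
                                  digits = 2) {
  model_column <- match.arg(model_column)
  criterion <- match.arg(criterion)
  ratio_source <- match.arg(ratio_source)
  if (is.null(records) || nrow(records) == 0L) {
    stop("records must be non-empty", call. = FALSE)
  }
  pred <- records[[paste0("predicted_aucr_", model_column)]]
  obs <- records$observed_aucr
  recomputed <- round(fold_ratio(pred, obs), digits)
  printed <- records[[paste0("printed_ratio_", model_column)]]
  ratio <- if (ratio_source == "recomputed") recomputed else printed
  alt <- if (ratio_source == "recomputed") printed else recomputed

  apply_crit <- function(r) {
    switch(criterion,
           twofold = twofold_pass(r, bounds_inclusive),
           guest = {
             lim <- guest_limit(obs, delta)
             # criterion is on predicted/observed relative to the
             # observed-ratio-dependent limit
             r >= 1 / lim & r <= lim
           })
  }
  pass <- apply_crit(ratio)
  pass_alt <- if (is.null(alt) || anyNA(alt)) {
    rep(NA, length(pass))
  } else {
    apply_crit(alt)
  }
  flags <- data.frame(victim = records$victim, ratio = ratio, pass = pass,
                      pass_alt_source = pass_alt,
                      flips = !is.na(pass_alt) & pass != pass_alt)
  structure(list(n = length(pass), n_pass = sum(pass),
                 pct_pass = round(100 * sum(pass) / length(pass)),
                 criterion = criterion, model_column = model_column,
                 ratio_source = ratio_source, delta = delta,
                 per_record_flags = flags),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %s model, %s criterion (%s ratios)\n",
              x$model_column, x$criterion, x$ratio_source))
  cat(sprintf("  %d/%d predictions pass (%d%%)\n", x$n_pass, x$n, x$pct_pass))
  fl <- x$per_record_flags
  if (any(fl$flips)) {
    cat("  records flipping with the alternative ratio source:",
        paste(fl$victim[fl$flips], collapse = ", "), "\n")
  }
  invisible(x)
}
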