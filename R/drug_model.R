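#' Construct and validate a drug model
#'
#' A `drug_model` is the full parameterization of one compound: its
#' physicochemical properties, compartmental disposition, clearance partition,
#' and (for perpetrators) CYP3A4 induction parameters. It is the unit the
#' simulation engine, the DDI orchestrator and the static model consume.
#'
#' All per-kg parameters (vc, clearances) are stored per kg and scaled by
#' subject body weight when the ODE system is built.
#'
#' @param name Non-empty compound name.
#' @param compound List of physicochemical properties: `molecular_weight`
#'   (g/mol), `log_d`, `pka_values` (list of `list(value=, type="acid"|"base")`),
#'   `aqueous_solubility` (mg/mL), `solubility_ph`, `particle_radius` (um),
#'   `precipitation_time` (s), `peff` (effective permeability, units of
#'   1e-4 cm/s), `rbp` (blood/plasma ratio), `fup` (fraction unbound, (0,1]).
#' @param disposition List: `vc` (L/kg), `k12`, `k21`, optionally `k13`,
#'   `k31` (all 1/h). `k13`/`k31` must be both present or both absent.
#' @param clearance List: `cl_cyp3a4_hepatic`, `cl_other_hepatic`, `cl_renal`
#'   (all L/h/kg, baseline/uninduced plasma clearances), `vmax_mode`
#'   ("linear" or "michaelis_menten"), `km` (mg/L; required in
#'   michaelis_menten mode), optionally `fm_cyp3a4` (fraction of total
#'   clearance via CYP3A4; filled in from the partition when absent) and `fg`
#'   (baseline intestinal availability, default 1).
#' @param induction Optional list (perpetrators only): `ec50` (uM, unbound),
#'   `emax` (fold-increase numerator), `kdeg_liver`, `kdeg_gut` (1/h enzyme
#'   degradation rate constants; defaults 0.019 and 0.030).
#'
#' @return A validated object of class `drug_model`.
#' @seealso [load_drug_model()], [rifampicin_model()]
#' @export
drug_model <- function(name, compound, disposition, clearance,
                       induction = NULL) {
  dm <- structure(
    list(name = name, compound = compound, disposition = disposition,
         clearance = clearance, induction = induction),
    class = "drug_model"
  )
  validate_drug_model(dm)
}

fail_schema <- function(field) {
  stop(sprintf("drug model schema error: missing or non-numeric field '%s'",
               field), call. = FALSE)
}

fail_valid <- function(msg) {
  stop(sprintf("drug model validation error: %s", msg), call. = FALSE)
}

need_num <- function(block, field, where) {
  v <- block[[field]]
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    fail_schema(paste0(where, "$", field))
  }
  as.numeric(v)
}

validate_drug_model <- function(dm) {
  if (!is.character(dm$name) || length(dm$name) != 1L || !nzchar(dm$name)) {
    fail_valid("name must be a non-empty string")
  }
  cp <- dm$compound
  for (f in c("molecular_weight", "rbp", "fup")) need_num(cp, f, "compound")
  if (cp$molecular_weight <= 0) fail_valid("molecular_weight must be > 0")
  if (cp$fup <= 0 || cp$fup > 1) fail_valid("fup must be in (0, 1]")
  if (cp$rbp <= 0) fail_valid("rbp must be > 0")
  cp$peff <- if (is.null(cp$peff)) 0 else need_num(cp, "peff", "compound")
  if (cp$peff < 0) fail_valid("peff must be >= 0")
  if (!is.null(cp$aqueous_solubility) && cp$aqueous_solubility < 0) {
    fail_valid("aqueous_solubility must be >= 0")
  }
  dm$compound <- cp

  dp <- dm$disposition
  need_num(dp, "vc", "disposition")
  if (dp$vc <= 0) fail_valid("vc must be > 0")
  for (f in c("k12", "k21")) {
    dp[[f]] <- if (is.null(dp[[f]])) 0 else need_num(dp, f, "disposition")
    if (dp[[f]] < 0) fail_valid(paste(f, "must be >= 0"))
  }
  if (is.null(dp$k13) != is.null(dp$k31)) {
    fail_valid("k13 and k31 must be both present or both absent")
  }
  if (!is.null(dp$k13)) {
    for (f in c("k13", "k31")) {
      if (need_num(dp, f, "disposition") < 0) fail_valid(paste(f, "must be >= 0"))
    }
  }
  dm$disposition <- dp

  cl <- dm$clearance
  for (f in c("cl_cyp3a4_hepatic", "cl_other_hepatic", "cl_renal")) {
    cl[[f]] <- if (is.null(cl[[f]])) 0 else need_num(cl, f, "clearance")
    if (cl[[f]] < 0) fail_valid(paste(f, "must be >= 0"))
  }
  cl$vmax_mode <- if (is.null(cl$vmax_mode)) "linear" else cl$vmax_mode
  if (!cl$vmax_mode %in% c("linear", "michaelis_menten")) {
    fail_valid("vmax_mode must be 'linear' or 'michaelis_menten'")
  }
  if (cl$vmax_mode == "michaelis_menten") {
    if (is.null(cl$km)) fail_schema("clearance$km")
    if (need_num(cl, "km", "clearance") <= 0) {
      fail_valid("km must be > 0 in michaelis_menten mode")
    }
  }
  cl$fg <- if (is.null(cl$fg)) 1 else need_num(cl, "fg", "clearance")
  if (cl$fg <= 0 || cl$fg > 1) fail_valid("fg must be in (0, 1]")
  cl_total <- cl$cl_cyp3a4_hepatic + cl$cl_other_hepatic + cl$cl_renal
  fm_implied <- if (cl_total > 0) cl$cl_cyp3a4_hepatic / cl_total else 0
  if (is.null(cl$fm_cyp3a4)) {
    cl$fm_cyp3a4 <- fm_implied
  } else {
    fm <- need_num(cl, "fm_cyp3a4", "clearance")
    if (fm < 0 || fm > 1) fail_valid("fm_cyp3a4 must be in [0, 1]")
    if (abs(fm - fm_implied) > 0.01) {
      fail_valid(sprintf(
        "fm_cyp3a4 (%.3f) inconsistent with clearance partition (%.3f)",
        fm, fm_implied))
    }
  }
  dm$clearance <- cl

  if (!is.null(dm$induction)) {
    ind <- dm$induction
    if (is.null(ind$kdeg_liver)) ind$kdeg_liver <- 0.019
    if (is.null(ind$kdeg_gut)) ind$kdeg_gut <- 0.030
    for (f in c("ec50", "emax", "kdeg_liver", "kdeg_gut")) {
      need_num(ind, f, "induction")
    }
    if (ind$ec50 <= 0) fail_valid("ec50 must be > 0")
    if (ind$emax < 0) fail_valid("emax must be >= 0")
    if (ind$kdeg_liver <= 0 || ind$kdeg_gut <= 0) {
      fail_valid("kdeg values must be > 0")
    }
    dm$induction <- ind
  }
  dm
}

#' Load a drug model from a JSON or YAML configuration file
#'
#' Parses a drug-model configuration (schema documented in
#' [drug_model()]), validates every invariant, and returns the normalized
#' `drug_model`. The format is chosen from the file extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Path to the configuration file.
#' @return A validated [drug_model()].
#' @examples
#' rif <- load_drug_model(system.file("extdata", "rifampicin.json",
#'                                    package = "pbpkddi"))
#' rif$induction$emax # 14.6
#' @export
load_drug_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("drug model config not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format (use .json, .yml or .yaml)", call. = FALSE)
  )
  for (blk in c("name", "compound", "disposition", "clearance")) {
    if (is.null(cfg[[blk]])) fail_schema(blk)
  }
  # flatten length-1 lists that jsonlite/yaml may produce
  unbox1 <- function(x) if (is.list(x)) lapply(x, unbox1) else x
  drug_model(name = cfg$name,
             compound = cfg$compound,
             disposition = cfg$disposition,
             clearance = cfg$clearance,
             induction = cfg$induction)
}

#' The packaged rifampicin perpetrator model
#'
#' Loads the shipped rifampicin parameterization: two-compartment disposition
#' (Vc 0.15145 L/kg, K12 1.4219 1/h, K21 1.7949 1/h), the three-way clearance
#' partition (CYP3A4-mediated hepatic 0.0179, other hepatic 0.0623, renal
#' 0.0169 L/h/kg) and the CYP3A4 induction parameters (EC50 0.8 uM,
#' Emax 14.6).
#'
#' @return A [drug_model()] with an induction block.
#' @export
rifampicin_model <- function() {
  load_drug_model(system.file("extdata", "rifampicin.json",
                              package = "pbpkddi", mustWork = TRUE))
}

#' Packaged synthetic exemplar victims
#'
#' Three illustrative victim models spanning CYP3A4 contribution
#' (fm = 0.25, 0.60, 0.95) and intestinal availability (fg = 1.0, 0.8, 0.6).
#' They are synthetic constructions for exercising and validating the
#' pipeline, not parameterizations of any published drug.
#'
#' @return A named list of three [drug_model()] objects.
#' @export
exemplar_victims <- function() {
  files <- c(low_fm = "victim_synthetic_low_fm.json",
             mid_fm = "victim_synthetic_mid_fm.json",
             high_fm = "victim_synthetic_high_fm.json")
  lapply(files, function(f) {
    load_drug_model(system.file("extdata", f, package = "pbpkddi",
                                mustWork = TRUE))
  })
}

#' @export
print.drug_model <- function(x, ...) {
  cl <- x$clearance
  cat(sprintf("<drug_model> %s\n", x$name))
  cat(sprintf("  MW %g g/mol | fup %g | Rbp %g | Peff %g x1e-4 cm/s\n",
              x$compound$molecular_weight, x$compound$fup, x$compound$rbp,
              x$compound$peff))
  ncomp <- 1L + (x$disposition$k12 > 0) + (!is.null(x$disposition$k13))
  cat(sprintf("  disposition: %d-compartment, Vc %g L/kg\n", ncomp,
              x$disposition$vc))
  cat(sprintf("  CL (L/h/kg): CYP3A4 %g (%s) | other %g | renal %g; fm %.3f, fg %g\n",
              cl$cl_cyp3a4_hepatic, cl$vmax_mode, cl$cl_other_hepatic,
              cl$cl_renal, cl$fm_cyp3a4, cl$fg))
  if (!is.null(x$induction)) {
    cat(sprintf("  induction: EC50 %g uM, Emax %g, kdeg liver/gut %g/%g 1/h\n",
                x$induction$ec50, x$induction$emax, x$induction$kdeg_liver,
                x$induction$kdeg_gut))
  }
  invisible(x)
}

#' Write a drug model back to a JSON configuration file
#'
#' @param dm A [drug_model()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_drug_model <- function(dm, path) {
  stopifnot(inherits(dm, "drug_model"))
  jsonlite::write_json(unclass(dm), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
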