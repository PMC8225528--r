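## Compound models.
##
## A drug is described by its physicochemistry (MW, logP, pKa set), plasma
## binding (fup, blood:plasma ratio, fetal fup), transporter kinetics
## (Michaelis-Menten Km/Vmax with location and direction), per-tissue
## model assignment (perfusion- vs permeability-limited), and PStc values
## for permeability-limited tissues (absolute mL/s, or specific
## mL/s per mL tissue). Drug files are YAML; every numeric field carries a
## machine-checkable provenance tag (printed | supplementary | literature |
## fitted | assumed | calibrated).

.PROVENANCE_LEVELS <- c("printed", "supplementary", "literature", "fitted",
                        "assumed", "calibrated")

#' Construct a drug parameter set
#'
#' @param name Compound name.
#' @param molecular_weight g/mol.
#' @param logP Octanol-water log partition coefficient.
#' @param pka List of `list(value =, type = "acid"|"base")` entries.
#' @param fup Fraction unbound in (maternal/adult) plasma, in (0, 1].
#' @param blood_plasma_ratio Blood:plasma concentration ratio.
#' @param fup_fetal Fraction unbound in fetal plasma (NULL = derive from
#'   the fetal albumin ratio at the simulated GA).
#' @param transporters List of [transporter_kinetics()] entries.
#' @param tissue_models Named character vector mapping tissues to
#'   `"perfusion"` or `"permeability"`.
#' @param pstc Named list of PStc entries, each
#'   `list(value =, units = "mL/s"|"mL/s/mL", ga_ref = NULL)`. Absolute
#'   values given at a reference GA are rescaled with tissue volume.
#' @param mrp4_postpartum_factor Multiplier applied to the kidney MRP4
#'   Vmax for postpartum/female model variants (1 = no adjustment).
#' @param provenance Optional named character vector of provenance tags.
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(name, molecular_weight, logP, pka, fup,
                            blood_plasma_ratio = 1, fup_fetal = NULL,
                            transporters = list(),
                            tissue_models = c(kidney = "permeability"),
                            pstc = list(),
                            mrp4_postpartum_factor = 1,
                            provenance = character()) {
  if (molecular_weight <= 0) abort("`molecular_weight` must be positive.")
  if (fup <= 0 || fup > 1) abort("`fup` must be in (0, 1].")
  if (!is.null(fup_fetal) && (fup_fetal <= 0 || fup_fetal > 1)) {
    abort("`fup_fetal` must be in (0, 1].")
  }
  for (ps in pstc) {
    if (ps$value <= 0) abort("All PStc values must be positive.")
  }
  bad <- setdiff(unname(provenance), .PROVENANCE_LEVELS)
  if (length(bad)) {
    abort(paste("Unknown provenance tag(s):", paste(bad, collapse = ", ")))
  }
  structure(
    list(name = name, molecular_weight = molecular_weight, logP = logP,
         pka = pka, fup = fup, blood_plasma_ratio = blood_plasma_ratio,
         fup_fetal = fup_fetal, transporters = transporters,
         tissue_models = tissue_models, pstc = pstc,
         mrp4_postpartum_factor = mrp4_postpartum_factor,
         provenance = provenance),
    class = "drug_parameters"
  )
}

#' Transporter kinetics entry
#'
#' @param name Transporter name (e.g. `"OAT3"`, `"MRP4"`).
#' @param location `"kidney_basolateral"`, `"kidney_apical"` or
#'   `"placenta_apical"`.
#' @param direction `"influx"` or `"efflux"`.
#' @param km_uM Michaelis constant, uM (> 0).
#' @param vmax_ug_h Maximal transport rate at the reference organ size,
#'   ug/h (>= 0).
#' @param vmax_cv Coefficient of variation of Vmax for population
#'   sampling (fraction; 1 = 100%).
#' @return A list of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(name, location, direction, km_uM,
                                 vmax_ug_h, vmax_cv = 1) {
  location <- match.arg(location,
    c("kidney_basolateral", "kidney_apical", "placenta_apical"))
  direction <- match.arg(direction, c("influx", "efflux"))
  if (km_uM <= 0) abort("`km_uM` must be positive.")
  if (vmax_ug_h < 0) abort("`vmax_ug_h` must be non-negative.")
  structure(list(name = name, location = location, direction = direction,
                 km_uM = km_uM, vmax_ug_h = vmax_ug_h, vmax_cv = vmax_cv),
            class = "transporter_kinetics")
}

.unwrap_field <- function(x, tag_store, key) {
  if (is.list(x) && !is.null(x$value)) {
    if (!is.null(x$provenance)) tag_store[[key]] <- x$provenance
    x$value
  } else x
}

#' Read a drug file
#'
#' Parses a YAML drug description (see the packaged `cefuroxime.yaml` /
#' `cefazolin.yaml` under `extdata/drugs` for the schema). Scalar fields
#' may be written as `{value: ..., provenance: ...}` pairs; provenance
#' tags are collected and validated.
#'
#' @param path Path to a YAML drug file, or the bare name of a packaged
#'   compound (`"cefuroxime"` or `"cefazolin"`).
#' @return A `drug_parameters` object.
#' @export
read_drug <- function(path) {
  if (!file.exists(path)) {
    candidate <- system.file("extdata", "drugs", paste0(path, ".yaml"),
                             package = "pregpbpk")
    if (nzchar(candidate)) path <- candidate
  }
  if (!file.exists(path)) abort(sprintf("Drug file not found: %s", path))
  raw <- yaml::read_yaml(path)
  tags <- new.env(parent = emptyenv())
  uw <- function(x, key) .unwrap_field(x, tags, key)

  pka <- lapply(raw$pka, function(p) {
    list(value = uw(p$value, "pka"), type = p$type)
  })
  transporters <- lapply(raw$transporters, function(tr) {
    transporter_kinetics(
      name = tr$name, location = tr$location, direction = tr$direction,
      km_uM = uw(tr$km_uM, paste0(tr$name, "_km")),
      vmax_ug_h = uw(tr$vmax_ug_h, paste0(tr$name, "_vmax")),
      vmax_cv = uw(tr$vmax_cv %||% 1, paste0(tr$name, "_vmax_cv"))
    )
  })
  pstc <- lapply(raw$pstc, function(ps) {
    list(value = ps$value$value %||% ps$value,
         units = ps$units, ga_ref = ps$ga_ref %||% NULL)
  })
  for (nm in names(raw$pstc)) {
    pv <- raw$pstc[[nm]]$value
    if (is.list(pv) && !is.null(pv$provenance)) {
      tags[[paste0("pstc_", nm)]] <- pv$provenance
    }
  }
  drug_parameters(
    name = raw$name,
    molecular_weight = uw(raw$molecular_weight, "molecular_weight"),
    logP = uw(raw$logP, "logP"),
    pka = pka,
    fup = uw(raw$fup, "fup"),
    blood_plasma_ratio = uw(raw$blood_plasma_ratio, "blood_plasma_ratio"),
    fup_fetal = if (is.null(raw$fup_fetal)) NULL else uw(raw$fup_fetal, "fup_fetal"),
    transporters = transporters,
    tissue_models = unlist(raw$tissue_models),
    pstc = pstc,
    mrp4_postpartum_factor = uw(raw$mrp4_postpartum_factor %||% 1,
                                "mrp4_postpartum_factor"),
    provenance = unlist(as.list(tags))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance audit of a drug parameter set
#'
#' @param drug A `drug_parameters` object.
#' @return Tibble with columns `field`, `provenance`.
#' @export
drug_provenance <- function(drug) {
  stopifnot(inherits(drug, "drug_parameters"))
  tibble::tibble(field = names(drug$provenance),
                 provenance = unname(drug$provenance))
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s | MW %.1f | logP %.2f | fup %.3f | %d transporter(s)\n",
              x$name, x$molecular_weight, x$logP, x$fup,
              length(x$transporters)))
  invisible(x)
}

# Km in internal concentration units (ug/mL) from uM
.km_ugml <- function(km_uM, mw) km_uM * mw / 1000

.get_transporter <- function(drug, name) {
  for (tr in drug$transporters) if (tr$name == name) return(tr)
  NULL
}
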