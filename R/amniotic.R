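## Amniotic fluid exchange pathways.
##
## Four active pathways (fetal urination into the amniotic sac, fetal
## lung/oral/nasal secretion, fetal swallowing, and active intramembranous
## uptake into fetal blood across placenta/membranes) plus one passive
## transmembranous pathway (amniotic fluid <-> uterine wall). The active
## pathways obey the homeostasis constraint
##     urinary_rate + k_sec = k_sw + k_intram
## by construction. Term reference values (L/day at the 3.32 kg reference
## birth weight) average the ovine literature, rebalanced so each side of
## the constraint sums to 1.46 L/day; each rate scales linearly with
## fetal weight and is zero before 9 weeks GA (urine production onset).

# Term reference rates, L/day at the reference birth weight. The split of
# the 1.46 L/day total between pathways is configurable; defaults below.
.amniotic_defaults <- c(
  urinary_rate = 1.13,
  k_sec        = 0.33,
  k_sw         = 0.86,
  k_intram     = 0.60,
  k_trans      = 0.26
)

#' Amniotic fluid pathway rate constants
#'
#' Evaluates the five fluid-exchange rate constants (L/day) at a
#' gestational age and fetal weight. Active rates are the term reference
#' values normalized by the 3.32 kg reference birth weight and multiplied
#' by the current fetal weight; all active rates are zero before 9 weeks
#' GA. Inflow (urinary + secretion) always equals outflow (swallowing +
#' intramembranous).
#'
#' @param ga Gestational age in weeks.
#' @param fetal_weight Fetal body weight in kg (>= 0).
#' @param reference Named numeric vector of term reference rates (L/day at
#'   the reference weight) with elements `urinary_rate`, `k_sec`, `k_sw`,
#'   `k_intram`, `k_trans`. Defaults keep `urinary_rate + k_sec = 1.46`.
#' @return An object of class `amniotic_rates`: named list of the five
#'   rates in L/day plus `ga` and `fetal_weight`.
#' @examples
#' r <- amniotic_rates(40, 3.32)
#' r$urinary_rate + r$k_sec   # 1.46 L/day
#' @export
amniotic_rates <- function(ga, fetal_weight,
                           reference = .amniotic_defaults) {
  if (!is.numeric(ga) || ga < 0 || ga > 42) abort("`ga` must be in [0, 42].")
  if (!is.numeric(fetal_weight) || fetal_weight < 0) {
    abort("`fetal_weight` must be non-negative.")
  }
  ref <- .amniotic_defaults
  ref[names(reference)] <- reference
  inflow <- ref[["urinary_rate"]] + ref[["k_sec"]]
  outflow <- ref[["k_sw"]] + ref[["k_intram"]]
  if (abs(inflow - outflow) > 1e-12) {
    # rebalance the outflow split to restore exact homeostasis
    ref[["k_sw"]] <- ref[["k_sw"]] * inflow / outflow
    ref[["k_intram"]] <- ref[["k_intram"]] * inflow / outflow
  }
  scale <- fetal_weight / REF_FETAL_BIRTH_WEIGHT_KG
  active <- if (ga < 9) 0 else scale
  structure(
    list(
      ga = ga, fetal_weight = fetal_weight,
      urinary_rate = ref[["urinary_rate"]] * active,
      k_sec = ref[["k_sec"]] * active,
      k_sw = ref[["k_sw"]] * active,
      k_intram = ref[["k_intram"]] * active,
      k_trans = ref[["k_trans"]] * scale
    ),
    class = "amniotic_rates"
  )
}

#' @export
print.amniotic_rates <- function(x, ...) {
  cat(sprintf(
    "<amniotic_rates> GA %g wk, fetus %.2f kg (L/day): urine %.3f + sec %.3f = sw %.3f + intram %.3f; trans %.3f\n",
    x$ga, x$fetal_weight, x$urinary_rate, x$k_sec, x$k_sw, x$k_intram,
    x$k_trans))
  invisible(x)
}

#' Passive transmembranous solute flux
#'
#' Signed solute flux between the uterine wall and the amniotic fluid,
#' driven by the free-concentration gradient; positive values flow into
#' the amniotic fluid.
#'
#' @param c_free_amniotic Free concentration in amniotic fluid (ug/mL).
#' @param c_free_uterus Free concentration in uterine tissue (ug/mL).
#' @param k_trans Transmembranous rate constant (L/day).
#' @return Flux in ug/day (`k_trans * (c_free_uterus - c_free_amniotic)`,
#'   with L/day x ug/mL expressed per 1000 mL).
#' @examples
#' transmembranous_flux(0.5, 2.0, 0.26)
#' @export
transmembranous_flux <- function(c_free_amniotic, c_free_uterus, k_trans) {
  if (any(k_trans < 0)) abort("`k_trans` must be non-negative.")
  if (any(c_free_amniotic < 0) || any(c_free_uterus < 0)) {
    abort("Concentrations must be non-negative.")
  }
  k_trans * 1000 * (c_free_uterus - c_free_amniotic)
}

#' Per-pathway solute fluxes around the amniotic fluid
#'
#' Computes the instantaneous drug flux (ug/day) carried by each exchange
#' pathway given the compartment concentrations. Bulk-fluid pathways
#' (urine, swallowing, secretion) entrain drug at the total concentration
#' of their source compartment; the membrane-mediated intramembranous and
#' transmembranous pathways pass free drug. Fetal urine carries drug at
#' the fetal renal clearance (fetal fup x fetal GFR) rather than at the
#' urinary fluid rate.
#'
#' @param conc Named list/vector of concentrations (ug/mL):
#'   `fetal_blood`, `fetal_tissue`, `amniotic`, `uterus_free`.
#' @param rates An [amniotic_rates()] object.
#' @param fetal_renal_cl Fetal renal clearance in L/day
#'   (fetal fup x fetal GFR, converted).
#' @return A tibble with columns `pathway`, `from`, `to`, `flux` (ug/day,
#'   positive in the `from -> to` direction).
#' @export
solute_pathway_fluxes <- function(conc, rates, fetal_renal_cl) {
  stopifnot(inherits(rates, "amniotic_rates"))
  conc <- as.list(conc)
  need <- c("fetal_blood", "fetal_tissue", "amniotic", "uterus_free")
  if (!all(need %in% names(conc))) {
    abort(paste("`conc` must name:", paste(need, collapse = ", ")))
  }
  tibble::tibble(
    pathway = c("urinary", "swallowing", "secretion", "intramembranous",
                "transmembranous"),
    from = c("fetal_blood", "amniotic", "fetal_tissue", "amniotic", "uterus"),
    to = c("amniotic", "fetal_tissue", "amniotic", "fetal_blood", "amniotic"),
    flux = c(
      fetal_renal_cl * 1000 * conc$fetal_blood,
      rates$k_sw * 1000 * conc$amniotic,
      rates$k_sec * 1000 * conc$fetal_tissue,
      rates$k_intram * 1000 * conc$amniotic,
      transmembranous_flux(conc$amniotic, conc$uterus_free, rates$k_trans)
    )
  )
}
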