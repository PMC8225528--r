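## Tissue-to-plasma partition coefficients and clearance primitives.
##
## Two mechanistic Kp methods are provided, matching common PBPK practice:
##  * a Rodgers-Rowland-family method with the measured-fup correction
##    ("Lukacova-style"), used for perfusion-limited tissues;
##  * an extracellular-space method of the Poulin-Theil family, used for
##    permeability-limited tissues, where only the interstitial space and
##    its albumin content equilibrate with plasma.
## Tissue composition fractions (extracellular/intracellular water, neutral
## lipid, neutral phospholipid, tissue:plasma albumin ratio) ship as a
## versioned CSV compiled from the standard published human tables.

.tissue_composition_cache <- new.env(parent = emptyenv())

#' Human tissue composition table
#'
#' Fractional extracellular water (`f_ew`), intracellular water (`f_iw`),
#' neutral lipid (`f_nl`), neutral phospholipid (`f_np`) and
#' tissue-to-plasma albumin ratio (`alb_ratio`) per tissue, compiled from
#' the published composition data underlying mechanistic Kp methods.
#'
#' @return A tibble keyed by `tissue` (includes a `plasma` row).
#' @export
tissue_composition <- function() {
  if (is.null(.tissue_composition_cache$tab)) {
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "pregpbpk", mustWork = TRUE)
    .tissue_composition_cache$tab <- tibble::as_tibble(
      read.csv(path, stringsAsFactors = FALSE))
  }
  .tissue_composition_cache$tab
}

.composition_row <- function(tissue) {
  tab <- tissue_composition()
  row <- tab[tab$tissue == tissue, ]
  if (nrow(row) != 1) {
    abort(sprintf("No tissue composition entry for '%s'.", tissue))
  }
  as.list(row)
}

# Fraction neutral for a set of (pKa, type) pairs at a given pH.
.fraction_neutral <- function(pka_list, ph) {
  if (length(pka_list) == 0) return(1)
  ion <- 0
  for (p in pka_list) {
    if (p$type == "acid") ion <- ion + 10^(ph - p$value)
    if (p$type == "base") ion <- ion + 10^(p$value - ph)
  }
  1 / (1 + ion)
}

#' Tissue partition coefficient, perfusion-limited tissues
#'
#' Mechanistic tissue-to-plasma partition coefficient for perfusion-limited
#' tissues (Rodgers-Rowland-family equations with the measured plasma
#' unbound fraction, i.e. the Lukacova-style variant): unbound drug
#' distributes into tissue water according to ionization at plasma pH 7.4
#' and intracellular pH 7.0, partitions into neutral lipid and
#' phospholipid via logP, and - for acids and neutrals - binds tissue
#' albumin in proportion to the tissue:plasma albumin ratio and the plasma
#' binding implied by fup.
#'
#' @param drug A [drug_parameters()] object.
#' @param tissue Tissue name present in [tissue_composition()], or a
#'   one-row list with the composition fields.
#' @return Kp (total tissue / total plasma concentration), > 0.
#' @export
kp_lukacova <- function(drug, tissue) {
  comp <- if (is.character(tissue)) .composition_row(tissue) else tissue
  pl <- .composition_row("plasma")
  P <- 10^drug$logP
  fn_p <- .fraction_neutral(drug$pka, 7.4)   # neutral fraction, plasma
  fn_iw <- .fraction_neutral(drug$pka, 7.0)  # neutral fraction, cell water
  fup <- drug$fup

  lip <- function(f_nl, f_np) P * f_nl + (0.3 * P + 0.7) * f_np
  # plasma-protein association beyond plasma water/lipid, attributed to
  # albumin; the same association scales into tissue by alb_ratio
  ka_alb <- max(1 / fup - 1 - lip(pl$f_nl, pl$f_np) * fn_p, 0)

  kpu <- comp$f_ew +
    (fn_p / fn_iw) * comp$f_iw +
    fn_p * lip(comp$f_nl, comp$f_np) +
    ka_alb * comp$alb_ratio
  kp <- kpu * fup
  if (!is.finite(kp) || kp <= 0) abort("Computed Kp is not positive.")
  kp
}

#' Tissue partition coefficient, extracellular method
#'
#' Poulin-Theil-family extracellular partitioning used for
#' permeability-limited tissues: only the interstitial (extracellular)
#' water and its albumin pool equilibrate with plasma, so
#' `Kp = fup * f_ew + (1 - fup) * alb_ratio`. Reduces to the tissue
#' extracellular water fraction for a fully unbound drug.
#'
#' @inheritParams kp_lukacova
#' @return Extracellular Kp (> 0).
#' @export
kp_poulin_theil_extracellular <- function(drug, tissue) {
  comp <- if (is.character(tissue)) .composition_row(tissue) else tissue
  kp <- drug$fup * comp$f_ew + (1 - drug$fup) * comp$alb_ratio
  if (!is.finite(kp) || kp <= 0) abort("Computed extracellular Kp is not positive.")
  kp
}

#' Renal filtration clearance
#'
#' Passive glomerular filtration clearance: fraction unbound in plasma
#' times the glomerular filtration rate.
#'
#' @param fup Fraction unbound in plasma.
#' @param gfr Glomerular filtration rate (mL/min).
#' @return Clearance in mL/min.
#' @examples
#' renal_filtration_clearance(0.09, 120)  # 10.8 mL/min
#' @export
renal_filtration_clearance <- function(fup, gfr) {
  if (any(fup < 0) || any(gfr < 0)) abort("Inputs must be non-negative.")
  fup * gfr
}

#' Michaelis-Menten transport rate
#'
#' Saturable carrier-mediated transport rate driven by the unbound
#' substrate concentration.
#'
#' @param c_unbound Unbound concentration (uM or ug/mL; must match `km`).
#' @param km Michaelis constant in the same units as `c_unbound` (> 0).
#' @param vmax Maximal transport rate (amount/time).
#' @return Transport rate `vmax * c / (km + c)`.
#' @examples
#' mm_rate(117, 117, 100)  # half of Vmax
#' @export
mm_rate <- function(c_unbound, km, vmax) {
  if (any(km <= 0)) abort("`km` must be positive.")
  if (any(c_unbound < 0) || any(vmax < 0)) abort("Inputs must be non-negative.")
  vmax * c_unbound / (km + c_unbound)
}
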