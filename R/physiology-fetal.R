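## Fetal growth and function curves.
##
## Fetal weight follows the published log-quadratic sonographic growth
## equation (Hadlock-type): ln(weight in g) = 0.578 + 0.332 GA - 0.00354 GA^2,
## which passes within 10% of the 3.32 kg reference birth weight at term.
## GFR, hematocrit and blood volume are extrapolated downward from
## term/preterm infant data with smooth forms floored at zero; urine
## production (hence fetal GFR) starts at 9 weeks GA. Amniotic fluid volume
## follows a gamma-shaped curve peaking near 33 weeks (~0.8 L) and
## declining slightly towards term.

.fetal_weight_kg <- function(ga) {
  if (ga <= 0) return(0)
  exp(0.578 + 0.332 * ga - 0.00354 * ga^2) / 1000
}

.amniotic_fluid_L <- function(ga) {
  if (ga <= 0) return(0)
  # peak 0.80 L at GA = 2.8 * 11.79 ~ 33 wk
  7.38e-4 * ga^2.8 * exp(-ga / 11.79)
}

.fetal_gfr_mlmin <- function(ga) {
  if (ga < 9) return(0)
  3.0 * ((ga - 9) / 31)^2.5
}

#' Fetal state at a gestational age
#'
#' All fetal anatomical/physiological quantities used by the fetal
#' sub-model: body weight and length, blood/tissue/placental volumes,
#' hematocrit, GFR, plasma-albumin ratio relative to the adult (used to
#' derive the fetal unbound fraction of a drug), and amniotic fluid
#' volume. Returns an all-zero state at `ga = 0`.
#'
#' @param ga Gestational age in weeks, in \[0, 42\].
#' @param fup Optional maternal (adult) fraction unbound of a drug; when
#'   supplied, the drug's fetal unbound fraction is computed from the fetal
#'   albumin ratio and returned in `fetal_fup`.
#' @return An object of class `fetal_state` (a named list).
#' @examples
#' fetal_state(40)
#' fetal_state(25, fup = 0.67)$fetal_fup
#' @export
fetal_state <- function(ga, fup = NULL) {
  if (!is.numeric(ga) || is.na(ga) || ga < 0 || ga > 42) {
    abort("`ga` must be in [0, 42] weeks.")
  }
  w <- .fetal_weight_kg(ga)
  blood <- 0.095 * w                      # ~95 mL/kg fetal blood
  hct <- if (ga <= 0) 0 else 0.50 * ga^1.2 / (ga^1.2 + 10^1.2)
  placenta_total <- .preg_curves$placenta_volume(ga)
  # fetal albumin rises from ~20% to ~75% of the adult level by term
  alb_ratio <- if (ga <= 0) 0 else 0.20 + 0.55 * .hill(ga, 25, 2.5)
  fetal_fup <- if (is.null(fup) || ga <= 0) NA_real_ else {
    1 / (1 + (1 / fup - 1) * alb_ratio)
  }
  structure(
    list(
      ga = ga,
      fetal_weight = w,
      fetal_height = 1.25 * ga,
      fetal_blood_volume = blood,
      fetal_tissue_volume = max(w - blood, 0),
      fetal_placenta_volume = placenta_total * 0.4,  # fetal-facing share
      fetal_hematocrit = hct,
      fetal_gfr = .fetal_gfr_mlmin(ga),
      fetal_albumin_ratio = alb_ratio,
      fetal_fup = fetal_fup,
      amniotic_fluid_volume = .amniotic_fluid_L(ga)
    ),
    class = "fetal_state"
  )
}

#' @export
print.fetal_state <- function(x, ...) {
  cat(sprintf(
    "<fetal_state> GA %g wk | weight %.3f kg | blood %.3f L | GFR %.2f mL/min | AF %.2f L\n",
    x$ga, x$fetal_weight, x$fetal_blood_volume, x$fetal_gfr,
    x$amniotic_fluid_volume))
  invisible(x)
}
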