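## Gestational-age scaling of the maternal physiology.
##
## Each pregnancy-dependent quantity is expressed as baseline x ratio(GA)
## or baseline + increment(GA), with ratio(0) = 1 and increment(0) = 0
## exactly, so the GA = 0 physiology is bit-identical to the non-pregnant
## baseline. The curve shapes are smooth saturating (Hill-type) or
## monotone-cubic forms calibrated to the well-established longitudinal
## landmarks of normal singleton pregnancy:
##   plasma volume  +~45% by term          hematocrit 0.40 -> ~0.34
##   GFR            +~50% by mid-gestation uterus 0.08 -> ~1.1 kg
##   placenta       ~0.65 kg at term       kidney volume +~30%
##   serum albumin  -~22% at term          AGP -~10%
## See the methods vignette for sources and rationale; curves are locked
## by regression tests.

# Smooth onset function: exactly 0 at ga = 0, -> 1 for large ga.
.hill <- function(ga, ga50, h) ga^h / (ga50^h + ga^h)

# Averaged cumulative gestational weight gain (kg) for underweight, normal
# and overweight women combined (obese excluded); knots follow the pooled
# percentile data, interpolated with a monotone (Hyman-filtered) cubic.
.wg_knots_ga <- c(0, 8, 13, 20, 25, 30, 35, 40, 42)
.wg_knots_kg <- c(0, 0.6, 1.9, 4.3, 6.3, 8.7, 11.2, 13.6, 14.4)
.wg_spline <- splinefun(.wg_knots_ga, .wg_knots_kg, method = "hyman")

#' Gestational weight gain
#'
#' Cumulative maternal weight gain (kg) at a gestational age, averaged over
#' underweight, normal-weight and overweight pre-pregnancy BMI classes.
#' Smooth, non-negative and non-decreasing; 0 at GA = 0. Total body weight
#' is `weight + weight_gain`.
#'
#' @param spec A [subject_spec()].
#' @return Weight gain in kg.
#' @examples
#' weight_gain(subject_spec(25, 62, 163, gestational_age = 25))
#' @export
weight_gain <- function(spec) {
  stopifnot(is_subject_spec(spec))
  ga <- spec$gestational_age
  if (ga == 0) return(0)
  .wg_spline(ga)
}

# GA-dependent ratio/increment curves (exactly baseline at GA = 0)
.preg_curves <- list(
  plasma_volume_ratio = function(ga) 1 + 0.45 * .hill(ga, 27, 3.2),
  hct_ratio           = function(ga) 1 - 0.155 * .hill(ga, 30, 3),
  gfr_ratio           = function(ga) 1 + 0.50 * .hill(ga, 14, 2.5),
  kidney_ratio        = function(ga) 1 + 0.30 * .hill(ga, 20, 2),
  brain_ratio         = function(ga) 1 - 0.03 * .hill(ga, 30, 3),
  albumin_ratio       = function(ga) 1 - 0.22 * .hill(ga, 24, 2.5),
  agp_ratio           = function(ga) 1 - 0.10 * .hill(ga, 24, 2.5),
  uterus_increment    = function(ga) 1.02 * .hill(ga, 26, 2.8),
  placenta_volume     = function(ga) 0.65 * (ga / 40)^1.6,
  # maternal placental plasma-flow fraction of cardiac output (~10% at term)
  placenta_flow_frac  = function(ga) 0.10 * .hill(ga, 30, 2.5),
  uterus_flow_frac_add = function(ga) 0.02 * .hill(ga, 26, 2.8)
)

#' Maternal physiology at a gestational age
#'
#' Evaluates every maternal anatomical and physiological model parameter
#' for a subject: per-tissue volumes (L) and plasma flows (L/h), cardiac
#' output, plasma volume, hematocrit, GFR, and plasma-protein ratios.
#' Organs that do not change with pregnancy (heart, spleen, liver, lung,
#' muscle) stay at their non-pregnant values; skin, adipose, cardiac output
#' and rest-of-body are recomputed from the current (gained) body weight by
#' the baseline allometric rules; kidney, uterus, placenta, brain, plasma
#' volume, hematocrit, GFR and protein concentrations follow published
#' pregnancy trends. At GA = 0 the result equals [baseline_physiology()]
#' exactly.
#'
#' @param spec A [subject_spec()].
#' @return An object of class `maternal_physiology`: a list with `volumes`,
#'   `plasma_flows` (both named), `cardiac_output`, `plasma_volume`,
#'   `blood_volume`, `hematocrit`, `gfr` (mL/min), `albumin_ratio`,
#'   `agp_ratio`, `total_body_weight`, `weight_gain`, and the `subject`.
#' @examples
#' maternal_physiology(subject_spec(30, 61.7, 163, gestational_age = 25))
#' @export
maternal_physiology <- function(spec) {
  stopifnot(is_subject_spec(spec))
  ga <- spec$gestational_age
  wg <- weight_gain(spec)
  tbw <- spec$weight + wg

  base <- baseline_physiology(spec, weight_override = tbw)
  vols <- base$volumes
  cv <- .preg_curves

  vols[["kidney"]] <- vols[["kidney"]] * cv$kidney_ratio(ga)
  vols[["brain"]]  <- vols[["brain"]] * cv$brain_ratio(ga)
  vols[["uterus"]] <- vols[["uterus"]] + cv$uterus_increment(ga)
  placenta <- cv$placenta_volume(ga)
  vols[["placenta"]] <- placenta * 0.6   # maternal-facing share of placenta

  hct <- base$hematocrit * cv$hct_ratio(ga)
  pv <- baseline_physiology(spec)$plasma_volume * cv$plasma_volume_ratio(ga)
  blood <- pv / (1 - hct)

  co <- base$cardiac_output
  plasma_frac <- 1 - hct
  ff <- .flow_fractions(spec$sex)
  flows <- ff * co * plasma_frac
  flows[["uterus"]] <- flows[["uterus"]] +
    cv$uterus_flow_frac_add(ga) * co * plasma_frac
  flows[["placenta"]] <- cv$placenta_flow_frac(ga) * co * plasma_frac
  flows[["rest"]] <- co * plasma_frac - sum(flows)

  # rest-of-body keeps total mass closed against the gained weight
  fetal <- fetal_state(ga)
  nonrest <- sum(vols[names(vols) != "rest"])
  accounted <- nonrest + blood + fetal$fetal_weight +
    fetal$amniotic_fluid_volume + fetal$fetal_placenta_volume
  vols[["rest"]] <- max(tbw - accounted, 0.02 * tbw)

  structure(
    list(
      subject = spec,
      total_body_weight = tbw,
      weight_gain = wg,
      volumes = vols,
      plasma_flows = flows,
      cardiac_output = co,
      blood_volume = blood,
      plasma_volume = pv,
      hematocrit = hct,
      gfr = base$gfr * cv$gfr_ratio(ga),
      albumin_ratio = cv$albumin_ratio(ga),
      agp_ratio = cv$agp_ratio(ga)
    ),
    class = "maternal_physiology"
  )
}

#' @export
print.maternal_physiology <- function(x, ...) {
  cat(sprintf(
    "<maternal_physiology> GA %g wk | TBW %.1f kg (gain %.1f) | GFR %.1f mL/min | Hct %.3f\n",
    x$subject$gestational_age, x$total_body_weight, x$weight_gain,
    x$gfr, x$hematocrit))
  invisible(x)
}

#' Scale a transporter Vmax with organ size
#'
#' Transporter expression is assumed constant per gram of tissue, so the
#' whole-organ maximal transport rate scales proportionally with the
#' organ-volume ratio (e.g. the pregnancy-enlarged kidney relative to the
#' non-pregnant kidney).
#'
#' @param baseline_vmax Maximal transport rate at the reference organ size
#'   (any amount/time unit).
#' @param organ_volume_ratio Current organ volume / reference organ volume.
#' @return Scaled Vmax in the units of `baseline_vmax`.
#' @examples
#' scale_transporter_expression(100, 1.3)
#' @export
scale_transporter_expression <- function(baseline_vmax, organ_volume_ratio) {
  if (!is.numeric(baseline_vmax) || any(baseline_vmax <= 0)) {
    abort("`baseline_vmax` must be positive.")
  }
  if (!is.numeric(organ_volume_ratio) || any(organ_volume_ratio <= 0)) {
    abort("`organ_volume_ratio` must be positive.")
  }
  baseline_vmax * organ_volume_ratio
}

#' Tidy physiology snapshot
#'
#' Flattens a maternal physiology object into a long table
#' (parameter, value, units) for auditing or CSV export.
#'
#' @param x A `maternal_physiology` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `units`.
#' @export
tidy.maternal_physiology <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(parameter = paste0("volume_", names(x$volumes)),
                   value = unname(x$volumes), units = "L"),
    tibble::tibble(parameter = paste0("plasma_flow_", names(x$plasma_flows)),
                   value = unname(x$plasma_flows), units = "L/h"),
    tibble::tibble(
      parameter = c("total_body_weight", "weight_gain", "cardiac_output",
                    "blood_volume", "plasma_volume", "hematocrit", "gfr",
                    "albumin_ratio", "agp_ratio"),
      value = c(x$total_body_weight, x$weight_gain, x$cardiac_output,
                x$blood_volume, x$plasma_volume, x$hematocrit, x$gfr,
                x$albumin_ratio, x$agp_ratio),
      units = c("kg", "kg", "L/h", "L", "L", "fraction", "mL/min", "", "")
    )
  )
}
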