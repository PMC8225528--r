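## Non-pregnant baseline physiology generator.
##
## A standard reference-human parameterization in the spirit of the ICRP
## reference adult: organ masses as sex-specific fractions of body weight
## (brain held at a fixed reference mass, it does not track body size in
## adults), allometric cardiac output, and regional blood-flow fractions.
## All downstream pregnancy scaling is expressed relative to this baseline,
## so at GA = 0 the maternal physiology reduces to these values exactly.

# Organ mass fractions of body weight (density taken as 1 g/mL).
# Female column anchored at the 60-kg reference woman, male at the
# 73-kg reference man.
.organ_fractions <- function(sex) {
  if (sex == "female") {
    c(lung = 0.0070, heart = 0.00417, spleen = 0.00217, liver = 0.0233,
      kidney = 0.00458, skin = 0.0383, adipose = 0.3170, muscle = 0.2920,
      uterus = 0.00133)
  } else {
    c(lung = 0.00685, heart = 0.00452, spleen = 0.00205, liver = 0.0247,
      kidney = 0.00425, skin = 0.0356, adipose = 0.1990, muscle = 0.3970,
      uterus = 0)
  }
}

# Regional blood-flow fractions of cardiac output at rest; the remainder
# is assigned to the rest-of-body compartment.
.flow_fractions <- function(sex) {
  if (sex == "female") {
    c(heart = 0.050, spleen = 0.030, liver = 0.270, kidney = 0.170,
      skin = 0.050, adipose = 0.085, muscle = 0.120, brain = 0.120,
      uterus = 0.010)
  } else {
    c(heart = 0.040, spleen = 0.030, liver = 0.255, kidney = 0.190,
      skin = 0.050, adipose = 0.050, muscle = 0.170, brain = 0.120,
      uterus = 0)
  }
}

# Fixed reference brain mass (kg) and hematocrit.
.brain_mass <- function(sex) if (sex == "female") 1.30 else 1.45
.baseline_hct <- function(sex) if (sex == "female") 0.400 else 0.440

# Cardiac output (L/h); allometric exponent 0.75 on body weight, anchored
# at ~5.7 L/min for the 70-kg man, women ~9% lower for the same size.
.cardiac_output <- function(weight, sex) {
  co <- 14.1 * weight^0.75
  if (sex == "female") co <- co * 0.91
  co
}

# Blood volume (L): ~76.7 mL/kg (male), 68.3 mL/kg (female).
.blood_volume <- function(weight, sex) {
  mlkg <- if (sex == "female") 68.3 else 76.7
  mlkg * weight / 1000
}

# Baseline GFR (mL/min), allometric on body weight.
.baseline_gfr <- function(weight, sex) {
  if (sex == "female") 110 * (weight / 60)^0.75 else 120 * (weight / 73)^0.75
}

#' Non-pregnant baseline physiology
#'
#' Generates the full set of organ volumes (L), tissue plasma flows (L/h),
#' cardiac output, blood/plasma volumes, hematocrit and GFR for a healthy
#' non-pregnant adult from age, body weight, height and sex. This is the
#' reference state every pregnancy-induced change is applied to.
#'
#' @param spec A [subject_spec()] (its `gestational_age` is ignored here).
#' @param weight_override Optional current body weight (kg) used for the
#'   size-tracking quantities (skin, adipose, cardiac output, rest-of-body);
#'   used internally by the pregnancy scaling, which recomputes those from
#'   the gained weight.
#' @return A list with elements `volumes` (named, L), `plasma_flows`
#'   (named, L/h), `cardiac_output` (L/h), `blood_volume`, `plasma_volume`
#'   (L), `hematocrit`, `gfr` (mL/min).
#' @export
baseline_physiology <- function(spec, weight_override = NULL) {
  stopifnot(is_subject_spec(spec))
  bw0 <- spec$weight
  bw <- if (is.null(weight_override)) bw0 else weight_override
  sex <- spec$sex

  fr <- .organ_fractions(sex)
  vols <- c(
    lung   = fr[["lung"]] * bw0,
    heart  = fr[["heart"]] * bw0,
    spleen = fr[["spleen"]] * bw0,
    liver  = fr[["liver"]] * bw0,
    kidney = fr[["kidney"]] * bw0,
    # skin and adipose track current body weight (allometric on size)
    skin    = fr[["skin"]] * bw,
    adipose = fr[["adipose"]] * bw,
    muscle  = fr[["muscle"]] * bw0,
    brain   = .brain_mass(sex),
    uterus  = fr[["uterus"]] * bw0
  )
  blood <- .blood_volume(bw0, sex)
  hct <- .baseline_hct(sex)
  specified <- sum(vols) + blood
  vols[["rest"]] <- max(bw - specified, 0.02 * bw)

  co <- .cardiac_output(bw, sex)
  ff <- .flow_fractions(sex)
  plasma_frac <- 1 - hct
  flows <- ff * co * plasma_frac
  # rest-of-body takes the residual plasma flow so regional flows always
  # sum to cardiac plasma output
  flows[["rest"]] <- co * plasma_frac - sum(flows)

  list(
    volumes = vols,
    plasma_flows = flows,
    cardiac_output = co,
    blood_volume = blood,
    plasma_volume = blood * plasma_frac,
    hematocrit = hct,
    gfr = .baseline_gfr(bw0, sex)
  )
}
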