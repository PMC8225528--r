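#' Describe a simulation subject
#'
#' Bundles the demographic covariates from which every physiological
#' parameter of the model is derived: age, pre-pregnancy body weight,
#' height, and gestational age (GA). GA = 0 denotes the non-pregnant (or
#' postpartum) state; male subjects are permitted only at GA = 0 and are
#' used for baseline healthy-volunteer models.
#'
#' @param age Age in years (>= 18 for maternal subjects).
#' @param weight Pre-pregnancy body weight in kg.
#' @param height Height in cm.
#' @param gestational_age Gestational age in weeks, in \[0, 42\].
#' @param sex `"female"` or `"male"`.
#' @return An object of class `subject_spec`.
#' @examples
#' subject_spec(30, 61.7, 163, gestational_age = 41)
#' subject_spec(30, 70, 176, sex = "male")
#' @export
subject_spec <- function(age, weight, height, gestational_age = 0,
                         sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!is.numeric(gestational_age) || is.na(gestational_age) ||
      gestational_age < 0 || gestational_age > 42) {
    abort("`gestational_age` must be in [0, 42] weeks.")
  }
  if (!is.numeric(weight) || weight <= 0) {
    abort("`weight` (pre-pregnancy) must be positive.")
  }
  if (!is.numeric(height) || height <= 0) {
    abort("`height` must be positive.")
  }
  if (gestational_age > 0 && age < 18) {
    abort("Maternal subjects must be at least 18 years old.")
  }
  if (gestational_age > 0 && sex == "male") {
    abort("Pregnant physiologies are female; use sex = \"female\".")
  }
  structure(
    list(age = as.numeric(age), weight = as.numeric(weight),
         height = as.numeric(height),
         gestational_age = as.numeric(gestational_age), sex = sex),
    class = "subject_spec"
  )
}

#' @export
print.subject_spec <- function(x, ...) {
  state <- if (x$gestational_age > 0) {
    sprintf("pregnant, %g wk GA", x$gestational_age)
  } else "non-pregnant"
  cat(sprintf("<subject_spec> %s, %g y, %g kg, %g cm (%s)\n",
              x$sex, x$age, x$weight, x$height, state))
  invisible(x)
}

is_subject_spec <- function(x) inherits(x, "subject_spec")
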