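## Virtual-population Monte-Carlo simulation.
##
## Virtual pregnant subjects are generated from a bivariate lognormal
## height/weight distribution (default correlation 0.5) for the sampled
## age, with the gestational weight gain applied at the requested GA.
## Physiological and drug parameters receive lognormal multipliers with
## stated CVs; transporter Vmax CV defaults to 100% (protein-abundance
## based), other parameters 10-20% where literature is silent.

#' Population simulation specification
#'
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param age_range Age range (years).
#' @param ga_range Gestational-age range (weeks); a single value fixes GA.
#' @param weight_mean,weight_cv Pre-pregnancy weight lognormal mean (kg)
#'   and CV (fraction).
#' @param height_mean,height_cv Height lognormal mean (cm) and CV.
#' @param hw_correlation Height-weight log-scale correlation.
#' @param cv_map Named CVs (fractions) for parameter multipliers. Defaults:
#'   `OAT3` and `MRP4` Vmax 1.0 (100%), `gfr` 0.15, `kp` 0.15.
#' @param seed Random seed (integer).
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects, age_range = c(25, 35),
                            ga_range = c(38, 41),
                            weight_mean = 62, weight_cv = 0.15,
                            height_mean = 163, height_cv = 0.04,
                            hw_correlation = 0.5,
                            cv_map = c(OAT3 = 1.0, MRP4 = 1.0,
                                       gfr = 0.15, kp = 0.15),
                            seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (any(cv_map < 0)) abort("All CVs must be >= 0.")
  if (diff(range(age_range)) < 0 || diff(range(ga_range)) < 0) {
    abort("Ranges must be non-empty.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         ga_range = ga_range, weight_mean = weight_mean,
         weight_cv = weight_cv, height_mean = height_mean,
         height_cv = height_cv, hw_correlation = hw_correlation,
         cv_map = cv_map, seed = as.integer(seed)),
    class = "population_spec"
  )
}

# lognormal with natural-scale mean 1 and CV cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Sample virtual pregnant subjects
#'
#' Draws `n_subjects` subjects: age uniform in range, height/weight from
#' a correlated bivariate lognormal, GA uniform in range, and lognormal
#' parameter multipliers per the CV map. Deterministic for a fixed seed.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per subject: demographic columns plus one
#'   `mult_*` column per entry in the CV map.
#' @export
sample_subjects <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  ga <- runif(n, spec$ga_range[1], spec$ga_range[2])

  sd_w <- sqrt(log(1 + spec$weight_cv^2))
  sd_h <- sqrt(log(1 + spec$height_cv^2))
  Sigma <- matrix(c(sd_h^2, spec$hw_correlation * sd_h * sd_w,
                    spec$hw_correlation * sd_h * sd_w, sd_w^2), 2)
  z <- MASS::mvrnorm(n, mu = c(log(spec$height_mean) - sd_h^2 / 2,
                               log(spec$weight_mean) - sd_w^2 / 2),
                     Sigma = Sigma)
  z <- matrix(z, ncol = 2)

  out <- tibble::tibble(
    subject = seq_len(n), age = age, gestational_age = ga,
    height = exp(z[, 1]), weight = exp(z[, 2])
  )
  for (nm in names(spec$cv_map)) {
    out[[paste0("mult_", nm)]] <- .rlnorm_cv(n, spec$cv_map[[nm]])
  }
  out
}

#' Run a Monte-Carlo population simulation
#'
#' Simulates every sampled subject under a common regimen and summarizes
#' percentile bands (5/25/50/75/95) of the observables on the shared time
#' grid. Failed subject simulations are recorded, excluded and warned
#' about.
#'
#' @param spec A [population_spec()].
#' @param drug A [drug_parameters()] object.
#' @param regimen A [dose_regimen()].
#' @param observables Compartments to band (default maternal plasma,
#'   fetal venous blood, amniotic fluid when present).
#' @param t_end,dt Simulation horizon and grid.
#' @param postpartum_adjusted Passed to [build_model()].
#' @param keep_subjects Keep per-subject simulation objects.
#' @return An object of class `population_result` with `bands` (tibble:
#'   `time`, `observable`, `p5`, `p25`, `p50`, `p75`, `p95`), `subjects`
#'   (the sampled cohort), `failures`, and optionally `sims`.
#' @export
run_population <- function(spec, drug, regimen,
                           observables = NULL, t_end = 24, dt = 0.2,
                           postpartum_adjusted = FALSE,
                           keep_subjects = FALSE) {
  cohort <- sample_subjects(spec)
  sims <- vector("list", nrow(cohort))
  failures <- integer(0)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    sims[[i]] <- tryCatch({
      subj <- subject_spec(row$age, row$weight, row$height,
                           gestational_age = row$gestational_age)
      get_mult <- function(nm) {
        if (nm %in% names(row)) row[[nm]] else 1
      }
      mult <- c(OAT3 = get_mult("mult_OAT3"), MRP4 = get_mult("mult_MRP4"))
      g <- build_model(subj, drug, postpartum_adjusted = postpartum_adjusted,
                       vmax_multipliers = mult)
      if ("mult_gfr" %in% names(row)) {
        # apply the GFR multiplier through the graph parameters
        g$params$gfr <- g$params$gfr * row[["mult_gfr"]]
        p <- g$params; n_tis <- length(p$tissues)
        g$rhs <- function(y, input_rate) .pbpk_rhs(y, p, n_tis, input_rate)
      }
      simulate_pbpk(g, regimen, t_end = t_end, dt = dt)
    }, error = function(e) e)
    if (inherits(sims[[i]], "error")) failures <- c(failures, i)
  }
  if (length(failures)) {
    warn(sprintf("%d subject simulation(s) failed and were excluded: %s",
                 length(failures), paste(failures, collapse = ", ")))
  }
  ok <- setdiff(seq_along(sims), failures)
  if (!length(ok)) abort("All subject simulations failed.")

  if (is.null(observables)) {
    observables <- intersect(c("ven", "f_ven", "amniotic"),
                             sims[[ok[1]]]$graph$state_names)
  }
  grid <- .conc_series(sims[[ok[1]]], observables[1])$time
  bands <- purrr::map_dfr(observables, function(comp) {
    mat <- vapply(ok, function(i) {
      cs <- .conc_series(sims[[i]], comp)
      approx(cs$time, cs$concentration, xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    qs <- t(apply(mat, 1, quantile, probs = c(.05, .25, .5, .75, .95),
                  names = FALSE))
    tibble::tibble(time = grid, observable = comp,
                   p5 = qs[, 1], p25 = qs[, 2], p50 = qs[, 3],
                   p75 = qs[, 4], p95 = qs[, 5])
  })

  structure(
    list(bands = bands, subjects = cohort, failures = failures,
         sims = if (keep_subjects) sims else NULL,
         spec = spec, drug = drug$name),
    class = "population_result"
  )
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result> %s | n = %d (%d failed) | observables: %s\n",
              x$drug, x$spec$n_subjects, length(x$failures),
              paste(unique(x$bands$observable), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.population_result <- function(x, ...) x$bands

#' One-sample-per-subject delivery-style sampling
#'
#' Mimics cord-blood/amniotic-fluid sampling at delivery: one observation
#' time per virtual subject, drawn uniformly from `window`.
#'
#' @param result A `population_result` created with `keep_subjects = TRUE`.
#' @param observable Compartment to sample.
#' @param window Sampling window (h).
#' @param seed Seed for the sampling times.
#' @return Tibble `subject`, `time_h`, `observable`, `value`.
#' @export
delivery_samples <- function(result, observable = "f_ven",
                             window = c(0.5, 6), seed = 1L) {
  stopifnot(inherits(result, "population_result"))
  if (is.null(result$sims)) {
    abort("Run the population with `keep_subjects = TRUE` to draw samples.")
  }
  set.seed(seed)
  ok <- setdiff(seq_along(result$sims), result$failures)
  times <- runif(length(ok), window[1], window[2])
  purrr::map2_dfr(ok, times, function(i, tt) {
    cs <- .conc_series(result$sims[[i]], observable)
    tibble::tibble(subject = i, time_h = tt, observable = observable,
                   value = approx(cs$time, cs$concentration, xout = tt)$y)
  })
}
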