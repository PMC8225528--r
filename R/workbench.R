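## Scenario files, synthetic observed data, and validation metrics.

#' Read a scenario file
#'
#' A scenario is a YAML (or JSON) document describing a complete
#' simulation: subject block (`age`, `weight`, `height`,
#' `gestational_age_weeks`, `sex`), `drug` (packaged compound name or file
#' path), `regimen` (`dose_mg`, `times_h`, `duration_h`), `t_end_h`,
#' `dt_h`, and optional `postpartum_adjusted`, `amniotic_reference`
#' overrides and an `observed_csv` reference. Packaged study fixtures live
#' under `extdata/scenarios`.
#'
#' @param path Path to a scenario file, or the bare name of a packaged
#'   scenario (e.g. `"cfx_41wk"`).
#' @return A list of class `pbpk_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    candidate <- system.file("extdata", "scenarios", paste0(path, ".yaml"),
                             package = "pregpbpk")
    if (nzchar(candidate)) path <- candidate
  }
  if (!file.exists(path)) abort(sprintf("Scenario file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  for (key in c("subject", "drug", "regimen")) {
    if (is.null(raw[[key]])) {
      abort(sprintf("Scenario is missing the required '%s' block.", key))
    }
  }
  sb <- raw$subject
  spec <- subject_spec(sb$age, sb$weight, sb$height,
                       gestational_age = sb$gestational_age_weeks %||% 0,
                       sex = sb$sex %||% "female")
  regimen <- dose_regimen(raw$regimen$dose_mg,
                          times = raw$regimen$times_h %||% 0,
                          duration = raw$regimen$duration_h %||% 0)
  structure(
    list(name = raw$name %||% sub("\\.[^.]+$", "", basename(path)),
         subject = spec,
         drug = raw$drug,
         regimen = regimen,
         t_end = raw$t_end_h %||% 24,
         dt = raw$dt_h %||% 0.1,
         postpartum_adjusted = isTRUE(raw$postpartum_adjusted),
         amniotic_reference = if (!is.null(raw$amniotic_reference))
           unlist(raw$amniotic_reference) else NULL,
         observed_csv = raw$observed_csv %||% NULL,
         notes = raw$notes %||% NULL),
    class = "pbpk_scenario"
  )
}

#' Run a scenario end to end
#'
#' Builds the model, simulates, and (optionally) writes the tidy
#' concentration CSV, a physiology snapshot CSV and a summary JSON to
#' `outdir`.
#'
#' @param scenario A `pbpk_scenario`, or a path/packaged name passed to
#'   [read_scenario()].
#' @param outdir Output directory (NULL = no files written).
#' @return The `pbpk_sim` result, invisibly when writing files.
#' @export
run_scenario <- function(scenario, outdir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "pbpk_scenario"))
  drug <- if (inherits(scenario$drug, "drug_parameters")) scenario$drug
          else read_drug(scenario$drug)
  graph <- build_model(scenario$subject, drug,
                       amniotic_reference = scenario$amniotic_reference,
                       postpartum_adjusted = scenario$postpartum_adjusted)
  sim <- simulate_pbpk(graph, scenario$regimen, t_end = scenario$t_end,
                       dt = scenario$dt)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tidy(sim),
              file.path(outdir, paste0(scenario$name, "_profiles.csv")),
              row.names = FALSE)
    write.csv(tidy(graph$physiology),
              file.path(outdir, paste0(scenario$name, "_physiology.csv")),
              row.names = FALSE)
    jsonlite::write_json(as.list(glance(sim)),
                         file.path(outdir, paste0(scenario$name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(sim))
  }
  sim
}

#' Synthesize observed concentration data from a simulation
#'
#' Perturbs simulated "truth" concentrations with multiplicative lognormal
#' noise on a sampling schedule; stands in for clinical datasets that are
#' published only as figures. Used by the parameter-recovery machinery.
#'
#' @param sim A `pbpk_sim` (the truth).
#' @param schedule Sampling times (h).
#' @param cv Lognormal CV of the noise (0 = exact).
#' @param observable Compartment sampled.
#' @param seed Random seed.
#' @return Tibble `time_h`, `observable`, `value`, `unit`.
#' @export
synthesize_observed <- function(sim, schedule, cv = 0.15,
                                observable = NULL, seed = 1L) {
  stopifnot(inherits(sim, "pbpk_sim"))
  observable <- observable %||% sim$graph$plasma_compartment
  truth <- .interp_log(sim, observable, schedule)
  set.seed(seed)
  noise <- .rlnorm_cv(length(schedule), cv)
  tibble::tibble(time_h = schedule, observable = observable,
                 value = truth * noise, unit = "ug/mL")
}

#' Prediction-accuracy metrics
#'
#' Absolute average fold error (AAFE, the geometric-mean fold discrepancy)
#' and the fraction of predictions within two-fold of the observations,
#' per observable. Predictions are interpolated linearly in
#' log-concentration at the observed times. Non-positive observed values
#' are excluded with a warning.
#'
#' @param sim A `pbpk_sim`.
#' @param observed Data frame with columns `time_h`, `value` and
#'   optionally `observable`.
#' @return An object of class `fit_metrics`: tibble with columns
#'   `observable`, `n`, `aafe`, `frac_within_2fold`.
#' @export
compute_fit_metrics <- function(sim, observed) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (is.null(observed$observable)) {
    observed$observable <- sim$graph$plasma_compartment
  }
  bad <- observed$value <= 0 | !is.finite(observed$value)
  if (any(bad)) {
    warn(sprintf("Excluding %d non-positive observed value(s).", sum(bad)))
    observed <- observed[!bad, ]
  }
  out <- observed |>
    dplyr::group_by(.data$observable) |>
    dplyr::group_modify(function(df, key) {
      pred <- .interp_log(sim, key$observable, df$time_h)
      fe <- abs(log10(pred / df$value))
      tibble::tibble(n = nrow(df), aafe = 10^mean(fe),
                     frac_within_2fold = mean(10^fe <= 2 + 1e-12))
    }) |>
    dplyr::ungroup()
  class(out) <- c("fit_metrics", class(out))
  out
}

#' Validate the packaged study fixtures
#'
#' Loads every packaged scenario, runs it, and checks that the outputs
#' satisfy the structural invariants (non-negative concentrations, mass
#' balance within tolerance).
#'
#' @param tol Mass-balance tolerance (relative).
#' @param t_end Optional horizon override for speed.
#' @return Tibble with one row per fixture: `name`, `ok`, `mass_balance`.
#' @export
validate_fixtures <- function(tol = 1e-6, t_end = NULL) {
  dir <- system.file("extdata", "scenarios", package = "pregpbpk")
  files <- list.files(dir, "\\.yaml$", full.names = TRUE)
  purrr::map_dfr(files, function(f) {
    sc <- read_scenario(f)
    if (!is.null(t_end)) sc$t_end <- t_end
    sim <- run_scenario(sc)
    mb <- max(abs(sim$mass_balance$residual))
    neg <- min(sim$profiles$amount)
    tibble::tibble(name = sc$name, ok = mb <= tol && neg >= 0,
                   mass_balance = mb)
  })
}
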