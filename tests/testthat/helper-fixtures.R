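# Shared fixtures: reference subjects and the packaged compounds.

cfx <- read_drug("cefuroxime")
cz <- read_drug("cefazolin")

male_70 <- subject_spec(30, 70, 176, sex = "male")
female_0 <- subject_spec(30, 61.7, 163, gestational_age = 0)
female_25 <- subject_spec(30, 61.7, 163, gestational_age = 25)
female_41 <- subject_spec(30, 61.7, 163, gestational_age = 41)

quick_sim <- function(graph, dose_mg = 750, t_end = 12, dt = 0.2, ...) {
  simulate_pbpk(graph, dose_regimen(dose_mg, ...), t_end = t_end, dt = dt)
}
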