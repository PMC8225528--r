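Package: pregpbpk
Title: Maternal-Fetal Physiologically Based Pharmacokinetic Modeling for
    Renally Cleared Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK)
    simulation engine for pregnancy. Scales maternal anatomy and physiology
    (tissue volumes, plasma volume, hematocrit, glomerular filtration rate,
    plasma proteins, cardiac output) continuously with gestational age,
    grows a four-compartment fetus with an amniotic-fluid compartment
    coupled through urinary, swallowing, secretion, intramembranous and
    transmembranous exchange pathways, and integrates the resulting
    maternal-fetal ODE system for intravenous dosing regimens. Renal
    elimination combines passive glomerular filtration with
    transporter-mediated tubular secretion (OAT3 influx, MRP4 efflux,
    Michaelis-Menten kinetics) in a permeability-limited kidney; the
    placenta can be switched to a two-sided permeability-limited barrier.
    Includes mechanistic tissue partition-coefficient methods, weighted
    least-squares parameter estimation, virtual-population Monte-Carlo
    simulation, scenario files, and cefuroxime and cefazolin reference
    compound models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
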