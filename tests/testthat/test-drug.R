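# Compound models, partition coefficients, clearance primitives.

neutral_probe <- function(logP = 0, fup = 1) {
  drug_parameters("probe", molecular_weight = 300, logP = logP,
                  pka = list(), fup = fup)
}

test_that("perfusion-limited Kp approaches the tissue/plasma water ratio for a neutral unbound probe", {
  tc <- tissue_composition()
  for (tis in c("muscle", "kidney", "heart")) {
    comp <- tc[tc$tissue == tis, ]
    water_ratio <- (comp$f_ew + comp$f_iw) /
      tc$f_ew[tc$tissue == "plasma"]
    kp <- kp_lukacova(neutral_probe(), tis)
    expect_lt(abs(kp - water_ratio) / water_ratio, 0.20, label = tis)
  }
})

test_that("Kp increases strictly with logP for a neutral compound", {
  kps <- vapply(c(-1, 0, 1, 2), function(lp)
    kp_lukacova(neutral_probe(logP = lp), "adipose"), numeric(1))
  expect_true(all(diff(kps) > 0))
  expect_true(all(kps > 0))
})

test_that("degenerate plasma-as-tissue composition returns Kp near 1", {
  # a 'tissue' with plasma's own composition must partition ~unity
  pl <- as.list(tissue_composition()[tissue_composition()$tissue == "plasma", ])
  pl$f_iw <- 0
  kp <- kp_lukacova(neutral_probe(), pl)
  expect_equal(kp, 0.945 + 0.0035 + 0.7 * 0.0023, tolerance = 0.05)
})

test_that("extracellular Kp reduces to f_ew at fup = 1 and follows its explicit fup dependence", {
  tc <- tissue_composition()
  f_ew_kid <- tc$f_ew[tc$tissue == "kidney"]
  alb_kid <- tc$alb_ratio[tc$tissue == "kidney"]
  expect_equal(kp_poulin_theil_extracellular(neutral_probe(), "kidney"),
               f_ew_kid, tolerance = 1e-12)
  # hand-evaluated oracle: Kp = fup * f_ew + (1 - fup) * alb_ratio
  for (fup in c(0.09, 0.5, 0.67)) {
    expect_equal(
      kp_poulin_theil_extracellular(neutral_probe(fup = fup), "kidney"),
      fup * f_ew_kid + (1 - fup) * alb_kid, tolerance = 1e-12)
  }
  expect_gt(kp_poulin_theil_extracellular(cfx, "kidney"), 0)
  expect_error(kp_poulin_theil_extracellular(cfx, "no_such_tissue"),
               "composition")
})

test_that("fixture Kps for the polar acids sit in a physiologically plausible band", {
  for (drug in list(cfx, cz)) {
    for (tis in c("muscle", "liver", "adipose", "brain", "heart", "skin")) {
      kp <- kp_lukacova(drug, tis)
      expect_gt(kp, 0.05)
      expect_lt(kp, 5)
    }
  }
})

test_that("renal filtration clearance is the fup x GFR product", {
  expect_equal(renal_filtration_clearance(0.09, 120), 10.8)
  expect_equal(renal_filtration_clearance(1, 87), 87)
  expect_equal(renal_filtration_clearance(0, 87), 0)
  expect_error(renal_filtration_clearance(-0.1, 100), "non-negative")
})

test_that("Michaelis-Menten rate saturates, is linear at low concentration, and rejects km = 0", {
  expect_equal(mm_rate(50, 50, 100), 50)
  expect_equal(mm_rate(1e9, 50, 100), 100, tolerance = 1e-6)
  c_low <- 0.5  # km/100
  expect_equal(mm_rate(c_low, 50, 100), 100 / 50 * c_low, tolerance = 0.01)
  expect_error(mm_rate(10, 0, 100), "positive")
  # monotone and Lipschitz on a grid (slope bounded by vmax/km)
  cc <- seq(0, 500, by = 1)
  v <- mm_rate(cc, 50, 100)
  expect_true(all(diff(v) >= 0))
  expect_lt(max(diff(v)), 100 / 50 + 1e-9)
})

test_that("packaged drug files carry machine-checkable provenance", {
  for (drug in list(cfx, cz)) {
    prov <- drug_provenance(drug)
    expect_gt(nrow(prov), 5)
    expect_true(all(prov$provenance %in%
      c("printed", "supplementary", "literature", "fitted", "assumed",
        "calibrated")))
  }
  # fitted Vmax values are flagged as calibration outputs
  prov_cz <- drug_provenance(cz)
  expect_equal(prov_cz$provenance[prov_cz$field == "MRP4_vmax"], "fitted")
  expect_equal(prov_cz$provenance[prov_cz$field == "fup"], "printed")
})

test_that("drug constructor enforces invariants", {
  expect_error(drug_parameters("x", -1, 0, list(), 0.5), "molecular_weight")
  expect_error(drug_parameters("x", 300, 0, list(), 1.5), "fup")
  expect_error(drug_parameters("x", 300, 0, list(), 0.5,
                               pstc = list(kidney = list(value = -2))),
               "PStc")
  expect_error(transporter_kinetics("OAT3", "kidney_basolateral", "influx",
                                    km_uM = 0, vmax_ug_h = 10), "km")
})
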