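# Amniotic fluid exchange pathways.

test_that("active pathway homeostasis holds exactly at every GA and weight", {
  for (ga in c(9, 15, 25, 33, 40, 42)) {
    w <- fetal_state(ga)$fetal_weight
    r <- amniotic_rates(ga, w)
    expect_equal(r$urinary_rate + r$k_sec, r$k_sw + r$k_intram,
                 tolerance = 1e-14)
    expect_true(all(unlist(r[c("urinary_rate", "k_sec", "k_sw",
                               "k_intram", "k_trans")]) >= 0))
  }
})

test_that("term reference rates sum to 1.46 L/day and scale linearly with weight", {
  r <- amniotic_rates(40, REF_FETAL_BIRTH_WEIGHT_KG)
  expect_equal(r$urinary_rate + r$k_sec, 1.46, tolerance = 1e-12)
  expect_equal(r$k_sw + r$k_intram, 1.46, tolerance = 1e-12)
  # half weight -> half rates (hand-derived: 1.46 * 1.66 / 3.32 = 0.73)
  r_half <- amniotic_rates(30, 1.66)
  expect_equal(r_half$urinary_rate + r_half$k_sec, 0.73, tolerance = 1e-12)
  w <- fetal_state(30)$fetal_weight
  r30 <- amniotic_rates(30, w)
  expect_equal(r30$urinary_rate / r$urinary_rate, w / 3.32, tolerance = 1e-12)
  expect_equal(r30$k_trans / r$k_trans, w / 3.32, tolerance = 1e-12)
})

test_that("all active pathways are silent before 9 weeks GA", {
  r <- amniotic_rates(8, 0.05)
  expect_identical(r$urinary_rate, 0)
  expect_identical(r$k_sec, 0)
  expect_identical(r$k_sw, 0)
  expect_identical(r$k_intram, 0)
  expect_gt(r$k_trans, 0)   # transmembranous is the only early pathway
  expect_error(amniotic_rates(30, -1), "non-negative")
})

test_that("a custom rate split is rebalanced to exact homeostasis", {
  r <- amniotic_rates(40, 3.32,
                      reference = c(urinary_rate = 1.2, k_sec = 0.26,
                                    k_sw = 1.0, k_intram = 1.0))
  expect_equal(r$urinary_rate + r$k_sec, 1.46, tolerance = 1e-12)
  expect_equal(r$k_sw + r$k_intram, r$urinary_rate + r$k_sec,
               tolerance = 1e-12)
})

test_that("transmembranous flux is signed, antisymmetric and linear", {
  expect_identical(transmembranous_flux(2, 2, 0.3), 0)
  expect_gt(transmembranous_flux(1, 2, 0.3), 0)     # into amniotic fluid
  expect_equal(transmembranous_flux(1, 2, 0.3),
               -transmembranous_flux(2, 1, 0.3))
  expect_equal(transmembranous_flux(2, 4, 0.3),
               2 * transmembranous_flux(1, 2, 0.3))
  expect_error(transmembranous_flux(1, 2, -0.1), "non-negative")
})

test_that("solute fluxes vanish with no drug and conserve a closed fetal subsystem", {
  r <- amniotic_rates(30, fetal_state(30)$fetal_weight)
  z <- solute_pathway_fluxes(list(fetal_blood = 0, fetal_tissue = 0,
                                  amniotic = 0, uterus_free = 0), r, 0.1)
  expect_true(all(z$flux == 0))

  # closed subsystem: fetal blood + tissue + amniotic fluid, no uterine
  # exchange, no elimination; total amount must be conserved over 48 h
  vols <- c(fb = 0.3, ft = 1.2, af = 0.6) # L
  cl_u <- 0.05                            # L/day fetal renal clearance
  rhs <- function(t, y, p) {
    conc <- y / (vols * 1000)
    fl <- solute_pathway_fluxes(
      list(fetal_blood = conc[1], fetal_tissue = conc[2], amniotic = conc[3],
           uterus_free = conc[3]),  # equal free conc: no transmembranous flux
      r, cl_u)
    f <- setNames(fl$flux, fl$pathway) / 24   # ug/day -> ug/h
    list(c(-f[["urinary"]] + f[["intramembranous"]],
           f[["swallowing"]] - f[["secretion"]],
           f[["urinary"]] + f[["secretion"]] - f[["swallowing"]] -
             f[["intramembranous"]]))
  }
  y0 <- c(1000, 0, 0)
  sol <- deSolve::lsoda(y0, seq(0, 48, 1), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  totals <- rowSums(sol[, -1])
  expect_lt(max(abs(totals - 1000)) / 1000, 1e-8)
})

test_that("constant fetal plasma forcing drives amniotic fluid to the analytic steady state", {
  r <- amniotic_rates(35, fetal_state(35)$fetal_weight)
  v_af <- 0.8 * 1000   # mL
  cl_u <- 0.08         # L/day
  cf <- 10             # ug/mL, held constant
  k_out <- (r$k_sw + r$k_intram + r$k_trans) * 1000 / 24  # mL/h
  k_in <- cl_u * 1000 / 24 * cf                            # ug/h
  rhs <- function(t, y, p) list(k_in - k_out * y / v_af)
  sol <- deSolve::lsoda(c(0), seq(0, 2000, 10), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  css_analytic <- k_in / k_out           # ug/mL at steady state
  expect_equal(unname(sol[nrow(sol), 2]) / v_af, css_analytic,
               tolerance = 1e-6)
  # monotone bounded approach: never overshoots the steady-state amount
  expect_true(all(sol[, 2] <= css_analytic * v_af + 1e-9))
})
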