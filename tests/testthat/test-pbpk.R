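# ODE core: graph assembly, analytic limits, mass balance, orderings.

test_that("one-compartment reduction matches the closed-form monoexponential to 0.1%", {
  V <- 13; CL <- 5  # L, L/h
  g <- linear_graph(c(central = V),
                    data.frame(from = "central", to = "urine", cl = CL))
  sim <- simulate_pbpk(g, dose_regimen(500), t_end = 10, dt = 0.1)
  cp <- plasma_concentration(sim)
  analytic <- (500 * 1000 / (V * 1000)) * exp(-CL / V * cp$time)
  idx <- cp$time > 0
  expect_lt(max(abs(cp$concentration[idx] - analytic[idx]) / analytic[idx]),
            1e-3)
})

test_that("two-compartment reduction matches the matrix-exponential solution to 0.1%", {
  V1 <- 10; V2 <- 20; CL <- 4; Q <- 6
  g <- linear_graph(
    c(central = V1, peripheral = V2),
    data.frame(from = c("central", "central", "peripheral"),
               to = c("urine", "peripheral", "central"),
               cl = c(CL, Q, Q)))
  sim <- simulate_pbpk(g, dose_regimen(500), t_end = 12, dt = 0.1)
  cp <- plasma_concentration(sim)
  # independent oracle: eigen-decomposition of the 2x2 rate matrix
  K <- matrix(c(-(CL + Q) / V1, Q / V2,
                Q / V1, -Q / V2), 2, byrow = TRUE)
  e <- eigen(K)
  a0 <- solve(e$vectors, c(500 * 1000, 0))
  analytic <- vapply(cp$time, function(t)
    Re((e$vectors %*% (a0 * exp(e$values * t)))[1]) / (V1 * 1000),
    numeric(1))
  idx <- cp$time > 0
  expect_lt(max(abs(cp$concentration[idx] - analytic[idx]) /
                  pmax(analytic[idx], 1e-9)), 1e-3)
})

test_that("zero clearance conserves the dose exactly", {
  g <- linear_graph(c(central = 10, peripheral = 30),
                    data.frame(from = c("central", "peripheral"),
                               to = c("peripheral", "central"),
                               cl = c(5, 5)))
  sim <- simulate_pbpk(g, dose_regimen(100), t_end = 24, dt = 0.5)
  totals <- sim$profiles |>
    dplyr::summarise(total = sum(.data$amount), .by = "time") |>
    dplyr::filter(.data$time > 0)   # t = 0 row precedes the bolus event
  expect_lt(max(abs(totals$total - 100 * 1000)) / (100 * 1000), 1e-8)
})

test_that("non-pregnant graphs carry no fetal or amniotic compartments", {
  g0 <- build_model(female_0, cfx)
  expect_false(any(c("f_ven", "f_art", "amniotic", "placenta_fet") %in%
                     g0$state_names))
  gm <- build_model(male_70, cfx)
  expect_false("uterus" %in% gm$state_names)
  g41 <- build_model(female_41, cfx)
  expect_true(all(c("f_ven", "f_art", "f_tissue", "placenta_mat",
                    "placenta_fet", "amniotic") %in% g41$state_names))
})

test_that("GA = 0 build is identical to the explicit non-pregnant model output", {
  g_a <- build_model(female_0, cfx, postpartum_adjusted = TRUE)
  g_b <- build_model(subject_spec(30, 61.7, 163), cfx,
                     postpartum_adjusted = TRUE)
  s_a <- quick_sim(g_a)
  s_b <- quick_sim(g_b)
  expect_identical(s_a$profiles$amount, s_b$profiles$amount)
})

test_that("placental barrier parameters follow the compound fixtures", {
  g41 <- build_model(female_41, cfx)
  expect_equal(g41$params$pstc_mat / 3600, 15.9, tolerance = 1e-12)
  expect_equal(g41$params$pstc_fet / 3600, 32400, tolerance = 1e-12)
  # absolute PStc values scale with placental volume away from 41 wk
  g39 <- build_model(subject_spec(30, 61.7, 163, gestational_age = 39), cfx)
  vol_ratio <- g39$params$v_pl_mat / g41$params$v_pl_mat
  expect_equal(g39$params$pstc_mat / g41$params$pstc_mat, vol_ratio,
               tolerance = 1e-12)
  # specific PStc: 1 mL/s per mL of placental sub-tissue
  gcz <- build_model(female_41, cz)
  expect_equal(gcz$params$pstc_mat / 3600, 1.0 * gcz$params$v_pl_mat,
               tolerance = 1e-12)
})

test_that("mass balance stays within 1e-6 for bolus and infusion dosing", {
  s1 <- simulate_pbpk(build_model(male_70, cfx),
                      dose_regimen(1000, 0, 3 / 60), t_end = 24, dt = 0.1)
  s2 <- simulate_pbpk(build_model(female_41, cz),
                      dose_regimen(1000, 0, 0.5), t_end = 12, dt = 0.1)
  s3 <- simulate_pbpk(build_model(female_25, cfx, postpartum_adjusted = TRUE),
                      dose_regimen(750, c(0, 8)), t_end = 16, dt = 0.1)
  for (s in list(s1, s2, s3)) {
    expect_lt(max(abs(s$mass_balance$residual)), 1e-6)
    expect_true(all(s$profiles$amount >= 0))
  }
})

test_that("plasma concentration scales linearly with dose in the low-concentration regime", {
  s_lo <- quick_sim(build_model(male_70, cfx), dose_mg = 1, t_end = 8)
  s_hi <- quick_sim(build_model(male_70, cfx), dose_mg = 2, t_end = 8)
  cp_lo <- plasma_concentration(s_lo)$concentration
  cp_hi <- plasma_concentration(s_hi)$concentration
  idx <- cp_lo > 1e-9
  expect_lt(max(abs(cp_hi[idx] / cp_lo[idx] - 2)), 0.002)
})

test_that("pregnancy increases systemic clearance and early urinary excretion", {
  for (drug in list(cfx, cz)) {
    adj <- drug$name == "cefuroxime"
    s0 <- quick_sim(build_model(female_0, drug, postpartum_adjusted = adj))
    s25 <- quick_sim(build_model(female_25, drug, postpartum_adjusted = adj))
    expect_gt(glance(s25)$clearance_L_h, glance(s0)$clearance_L_h)
    expect_gt(urinary_excretion_pct(s25, c(0, 8)),
              urinary_excretion_pct(s0, c(0, 8)))
  }
})

test_that("fetal peak is later and lower than maternal for both compounds", {
  for (drug in list(cfx, cz)) {
    adj <- drug$name == "cefuroxime"
    s <- quick_sim(build_model(female_41, drug, postpartum_adjusted = adj),
                   dt = 0.05)
    mat <- plasma_concentration(s)
    fet <- plasma_concentration(s, "f_ven")
    expect_lt(max(fet$concentration), max(mat$concentration))
    expect_gt(fet$time[which.max(fet$concentration)],
              mat$time[which.max(mat$concentration)])
  }
})

test_that("urinary excretion accounting handles windows and multi-dose references", {
  s <- quick_sim(build_model(male_70, cfx), t_end = 10)
  expect_equal(urinary_excretion_pct(s, c(0, 0)), 0)
  expect_gt(urinary_excretion_pct(s, c(0, 10)), 90)  # nearly all excreted
  expect_error(urinary_excretion_pct(s, c(0, 99)), "horizon")
  # per-interval reference: second-dose window relative to one dose
  s2 <- simulate_pbpk(build_model(male_70, cfx), dose_regimen(750, c(0, 8)),
                      t_end = 16, dt = 0.1)
  w2 <- urinary_excretion_pct(s2, c(8, 16))
  expect_gt(w2, 50)
  expect_lt(w2, 130)  # carries over some first-dose drug
})

test_that("infusion administration is honored by the event machinery", {
  s <- simulate_pbpk(build_model(male_70, cfx), dose_regimen(1000, 0, 1),
                     t_end = 6, dt = 0.05)
  cp <- plasma_concentration(s)
  expect_equal(cp$time[which.max(cp$concentration)], 1, tolerance = 0.1)
  expect_lt(max(abs(s$mass_balance$residual)), 1e-6)
})
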