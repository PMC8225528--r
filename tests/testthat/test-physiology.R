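# Maternal and fetal physiology scaling.

test_that("weight gain starts at zero, hits the mid-gestation landmark, and is monotone", {
  expect_identical(weight_gain(female_0), 0)
  gain25 <- weight_gain(subject_spec(25, 62, 163, gestational_age = 25))
  expect_gt(gain25, 4)   # development subject gained ~6 kg at 25 wk
  expect_lt(gain25, 8)
  ga <- seq(0, 42, by = 0.5)
  gains <- vapply(ga, function(g)
    weight_gain(subject_spec(30, 62, 163, gestational_age = g)), numeric(1))
  expect_true(all(diff(gains) >= 0))
  expect_true(all(gains >= 0))
  expect_gt(weight_gain(subject_spec(30, 62, 163, gestational_age = 41)),
            weight_gain(subject_spec(30, 62, 163, gestational_age = 20)))
})

test_that("subject validation rejects out-of-range inputs", {
  expect_error(subject_spec(30, 62, 163, gestational_age = 45), "gestational_age")
  expect_error(subject_spec(30, -5, 163), "weight")
  expect_error(subject_spec(16, 62, 163, gestational_age = 20), "18")
  expect_error(subject_spec(30, 70, 176, gestational_age = 20, sex = "male"),
               "female")
})

test_that("GA = 0 reduces exactly to the non-pregnant baseline", {
  preg0 <- maternal_physiology(female_0)
  base <- baseline_physiology(female_0)
  expect_identical(preg0$volumes[["kidney"]], base$volumes[["kidney"]])
  expect_identical(preg0$hematocrit, base$hematocrit)
  expect_identical(preg0$gfr, base$gfr)
  expect_identical(preg0$plasma_volume, base$plasma_volume)
  expect_identical(preg0$cardiac_output, base$cardiac_output)
  expect_identical(preg0$albumin_ratio, 1)
  expect_identical(preg0$volumes[["placenta"]], 0)
})

test_that("pregnancy raises GFR, dilutes hematocrit, expands plasma volume", {
  p0 <- maternal_physiology(female_0)
  p25 <- maternal_physiology(female_25)
  p38 <- maternal_physiology(subject_spec(30, 61.7, 163, gestational_age = 38))
  expect_gt(p25$gfr, p0$gfr)
  expect_lt(p38$hematocrit, p0$hematocrit)
  expect_gt(p38$plasma_volume, p0$plasma_volume)
  # frozen regression values lock the documented curves
  expect_equal(p25$hematocrit, 0.377273, tolerance = 1e-5)
  expect_equal(p25$plasma_volume, 3.027669, tolerance = 1e-5)
  expect_equal(p25$gfr, 157.8187, tolerance = 1e-5)
  expect_equal(p38$hematocrit, 0.358447, tolerance = 1e-5)
  expect_equal(p38$plasma_volume, 3.380752, tolerance = 1e-5)
})

test_that("GFR increases monotonically through mid-gestation and curves are continuous", {
  ga <- seq(0, 30, by = 0.25)
  gfr <- vapply(ga, function(g)
    maternal_physiology(subject_spec(30, 61.7, 163, gestational_age = g))$gfr,
    numeric(1))
  expect_true(all(diff(gfr) > 0))
  # continuity: no jump anywhere on a fine grid
  ga2 <- seq(0, 42, by = 0.05)
  for (fn in list(function(g) maternal_physiology(
         subject_spec(30, 61.7, 163, gestational_age = g))$hematocrit,
       function(g) fetal_state(g)$amniotic_fluid_volume)) {
    y <- vapply(ga2, fn, numeric(1))
    expect_lt(max(abs(diff(y))), 0.01)
  }
})

test_that("total body weight closes against weight gain and tissue increments", {
  for (ga in c(15, 25, 35, 41)) {
    s <- subject_spec(30, 61.7, 163, gestational_age = ga)
    p <- maternal_physiology(s)
    p0 <- maternal_physiology(female_0)
    f <- fetal_state(ga)
    expect_equal(p$total_body_weight, s$weight + p$weight_gain)
    incr <- (p$volumes[["uterus"]] - p0$volumes[["uterus"]]) +
      p$volumes[["placenta"]] + f$fetal_placenta_volume + f$fetal_weight +
      f$amniotic_fluid_volume + (p$plasma_volume - p0$plasma_volume) +
      (p$volumes[["skin"]] + p$volumes[["adipose"]] -
       p0$volumes[["skin"]] - p0$volumes[["adipose"]])
    expect_lt(incr, p$weight_gain * 1.15)
    expect_true(all(p$volumes > 0))
    expect_lte(sum(p$plasma_flows),
               p$cardiac_output * (1 - p$hematocrit) + 1e-9)
  }
})

test_that("fetal state matches term landmarks and grows monotonically", {
  f40 <- fetal_state(40)
  expect_lt(abs(f40$fetal_weight - 3.32) / 3.32, 0.10)
  expect_identical(fetal_state(0)$fetal_weight, 0)
  expect_identical(fetal_state(0)$amniotic_fluid_volume, 0)
  expect_identical(fetal_state(8)$fetal_gfr, 0)
  expect_gt(fetal_state(20)$fetal_gfr, 0)
  ga <- seq(9, 40, by = 0.5)
  for (field in c("fetal_weight", "fetal_blood_volume", "fetal_hematocrit",
                  "fetal_gfr")) {
    y <- vapply(ga, function(g) fetal_state(g)[[field]], numeric(1))
    expect_true(all(diff(y) >= 0), info = field)
    expect_true(all(y >= 0), info = field)
  }
  # amniotic fluid peaks before term and declines after
  afv <- vapply(ga, function(g) fetal_state(g)$amniotic_fluid_volume,
                numeric(1))
  expect_lt(afv[length(afv)], max(afv))
  expect_error(fetal_state(50), "ga")
})

test_that("fetal unbound fraction exceeds maternal (lower fetal albumin)", {
  f <- fetal_state(41, fup = 0.67)
  expect_gt(f$fetal_fup, 0.67)
  expect_lte(f$fetal_fup, 1)
})

test_that("transporter expression scales proportionally with organ volume", {
  expect_equal(scale_transporter_expression(100, 1.0), 100)
  expect_equal(scale_transporter_expression(100, 1.3), 130)
  expect_error(scale_transporter_expression(-1, 1), "positive")
  expect_error(scale_transporter_expression(100, 0), "positive")
  # pregnant kidney Vmax / baseline = kidney volume ratio at that GA
  p25 <- maternal_physiology(female_25)
  p0 <- maternal_physiology(female_0)
  ratio <- p25$volumes[["kidney"]] / p0$volumes[["kidney"]]
  g25 <- build_model(female_25, cfx)
  g0 <- build_model(female_0, cfx)
  expect_equal(g25$params$mrp4_vmax / g0$params$mrp4_vmax, ratio,
               tolerance = 1e-12)
})
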