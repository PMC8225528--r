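---
title: "Methods: a maternal-fetal PBPK model for renally cleared drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a maternal-fetal PBPK model for renally cleared drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregpbpk)
```

# What the model is

`pregpbpk` simulates the disposition of intravenously dosed, renally
cleared drugs in pregnant women and their fetuses. The maternal side is a
whole-body PBPK model: perfusion-limited tissues (heart, spleen, liver,
skin, adipose, muscle, brain, uterus, rest-of-body) arranged in parallel
between arterial and venous plasma, the lung in series, and a
permeability-limited kidney. During pregnancy the model grows a placenta
(split into maternal-facing and fetal-facing sub-tissues), a
four-compartment fetus (arterial blood, venous blood, lumped tissue, fetal
placenta) and an amniotic-fluid compartment. Everything is assembled by
`build_model()` from three ingredients evaluated at the subject's
gestational age (GA): `maternal_physiology()`, `fetal_state()` and
`amniotic_rates()`.

All quantities use a fixed unit convention: volumes L, flows L/h, GFR
reported in mL/min (converted internally), amounts µg, concentrations
µg/mL, time h, GA weeks.

# Physiology scaling

Every pregnancy-dependent maternal quantity is written as
`baseline x ratio(GA)` or `baseline + increment(GA)` with `ratio(0) = 1`
and `increment(0) = 0` *exactly*, so the GA = 0 model is bit-identical to
the non-pregnant baseline — a property the test suite asserts on the
simulation output itself.

The non-pregnant baseline is a standard reference-human generator:
sex-specific organ-mass fractions of body weight anchored at the 60-kg
reference woman and 73-kg reference man, a fixed adult brain mass,
allometric cardiac output (`14.1 x BW^0.75` L/h, 9% lower for women),
blood volume of 68-77 mL/kg and baseline GFR of 110-120 mL/min scaled
with `BW^0.75`. Regional blood flows are resting fractions of cardiac
output, with the rest-of-body compartment absorbing the residual so
tissue plasma flows always sum to cardiac plasma output.

The GA curves are smooth saturating (Hill-type) or monotone-cubic forms
calibrated to the established longitudinal landmarks of normal singleton
pregnancy rather than to any single regression table: plasma volume +45%
by term, hematocrit 0.40 falling to ~0.34, GFR +50% by mid-gestation (and
monotone through it), kidney volume +30%, uterus growing from 0.08 to
~1.1 kg, placenta ~0.65 kg at term, serum albumin -22%. Skin, adipose,
cardiac output and rest-of-body are recomputed from the *current* (gained)
body weight through the same allometric rules as the baseline; heart,
spleen, liver, lung and muscle stay at their pre-pregnancy values. Each
curve is locked by a regression test at frozen values so any future
refinement is a deliberate, visible change.

Gestational weight gain is a monotone (Hyman) cubic through knots
averaging the published percentile trajectories of underweight, normal
and overweight women (obese excluded): 0 at conception, ~6.3 kg at 25
weeks, ~13.6 kg at 40 weeks. Total body weight is pre-pregnancy weight
plus gain, and a closure rule keeps modeled mass consistent: the
rest-of-body volume is recomputed so that tissues, blood, fetus, placenta
and amniotic fluid never exceed the gained weight (the test suite checks
the increments stay within 15% of the gain).

Fetal weight follows the published log-quadratic sonographic growth
equation `ln(W g) = 0.578 + 0.332 GA - 0.00354 GA^2`, which gives 3.50-3.6
kg at term — within 10% of the 3.32 kg reference birth weight used to
normalize the amniotic exchange rates. Fetal blood is 95 mL/kg (40%
arterial, 60% venous), fetal hematocrit rises along a saturating curve to
~0.42 at term, and fetal GFR is zero before 9 weeks (urine production
onset) rising to ~3 mL/min at term as a smooth power of (GA - 9). The
fetal unbound fraction of a drug is derived from the fetal:adult albumin
ratio (0.2 rising to ~0.75 at term):
`fup_fetal = 1 / (1 + (1/fup - 1) x albumin_ratio)`, always above the
maternal `fup`. Amniotic fluid volume follows a gamma-shaped curve
`7.38e-4 GA^2.8 exp(-GA/11.79)` L peaking at ~0.80 L near 33 weeks and
declining slightly toward term.

# Amniotic fluid exchange

Five pathways connect the amniotic fluid to its surroundings: fetal
urination (into the sac), fetal lung/oral/nasal secretion (in), fetal
swallowing (out), active intramembranous uptake into fetal blood (out),
and passive transmembranous exchange with the uterine wall. The active
pathways satisfy the homeostasis constraint

    urinary_rate + k_sec = k_sw + k_intram

*by construction*: any user-supplied split is rebalanced so the outflow
side matches the inflow sum. The term reference values (L/day at the
3.32 kg reference weight) are urinary 1.13, secretion 0.33, swallowing
0.86, intramembranous 0.60 — averages of the ovine literature rebalanced
so each side sums to 1.46 L/day, the constraint treated as authoritative
(the two source totals, 1.26 and 1.51 L/day, do not average to it; we
keep 1.46 and note the discrepancy). Each rate scales linearly with fetal
weight over the reference weight and is zero before 9 weeks GA, leaving
transmembranous exchange as the only early pathway.

Solute transport distinguishes bulk-fluid from membrane-mediated
pathways: urine, swallowing and secretion entrain drug at the **total**
concentration of their source compartment (fluid movement carries all
dissolved drug), while the intramembranous and transmembranous pathways
pass **free** drug (membranes pass unbound molecules). Fetal urine
carries drug at the fetal renal clearance, `fup_fetal x fetal GFR`, not at
the urinary fluid rate. Swallowed drug is routed to the lumped fetal
tissue; with a single fetal tissue compartment this is equivalent to a
gut-then-blood route. The transmembranous constant `k_trans` is not
printed anywhere; the default (0.26 L/day at term, weight-scaled) is a
calibrated value chosen so the amniotic-fluid profile shape stays
reasonable, and is exposed in the configuration as such.

The amniotic fluid is a well-mixed compartment whose volume is imposed by
the GA curve rather than integrated from the fluid fluxes — integrating
the fluxes would drift against the published volume curve over
multi-day horizons.

# Drug model

A compound is described by molecular weight, logP, pKa set, plasma
unbound fraction (`fup`), blood:plasma ratio, transporter kinetics,
per-tissue model assignment and PStc values. Two partition-coefficient
methods are implemented:

* **Perfusion-limited tissues** use a Rodgers-Rowland-family equation
  with the measured plasma `fup` (the Lukacova-style variant): unbound
  drug distributes into tissue water with ionization at plasma pH 7.4 and
  intracellular pH 7.0, partitions into neutral lipid/phospholipid via
  logP, and binds tissue albumin in proportion to the tissue:plasma
  albumin ratio and the binding implied by `fup`.
* **Permeability-limited tissues** (kidney, placenta) use an
  extracellular method of the Poulin-Theil family,
  `Kp = fup x f_EW + (1 - fup) x alb_ratio`, reducing to the tissue
  extracellular water fraction for a fully unbound drug.

The tissue composition fractions ship as a versioned CSV compiled from
the standard published human tables. For the two packaged cephalosporins
(polar acids) the perfusion Kp values land in the 0.05-5 band, as they
should.

Renal elimination combines passive filtration (`fup x GFR`, drawn from
the kidney plasma space into a 15-mL tubular-filtrate compartment that
drains to urine at the GFR flow) with transporter-mediated secretion:
OAT3 influx across the basolateral membrane into the cell and MRP4
efflux from the cell into the filtrate, both Michaelis-Menten in the
unbound concentration. The passive basolateral PStc for these compounds
(1 mL/s per mL kidney) is high enough that the cell tracks the unbound
extracellular concentration; secretion is therefore MRP4-controlled in
practice, which is also why the postpartum five-fold MRP4 Vmax reduction
visibly slows urinary excretion. Transporter expression is assumed
constant per gram of kidney, so whole-organ Vmax scales with the
pregnancy kidney-volume ratio.

Packaged compound files (`cefuroxime.yaml`, `cefazolin.yaml`) tag every
numeric field with machine-checkable provenance
(`printed | supplementary | literature | fitted | assumed | calibrated`).
Cefazolin's Km values (OAT3 117 µM via the Ki approximation, MRP4
80.9 µM), its 9% `fup` compromise and the 1 mL/s/mL specific placental
PStc are printed values. Cefuroxime's OAT3/MRP4 Km is not printed; the
fixture uses 300 µM (tagged `assumed`), high enough that clinical unbound
concentrations stay below Km — consistent with the observed linear PK
across doses. Vmax values are calibration outputs by design: they were
fitted with the package's own machinery against the literature
renal-clearance targets (cefuroxime ~6.3-6.9 L/h, cefazolin ~4 L/h in
healthy adults) and carry provenance `fitted`.

# Placental transfer

Both validation compounds use a permeability-limited placenta: the
maternal-facing sub-tissue (60% of placental mass, perfused by the
maternal placental plasma flow, ~10% of cardiac output at term) exchanges
with the fetal-facing sub-tissue through the maternal-side PStc, and the
fetal side exchanges with fetal venous blood through the fetal-side PStc,
all on unbound concentrations. For cefuroxime the barriers are the fitted
absolute values at 41 weeks — 15.9 mL/s maternal, 32,400 mL/s fetal —
rescaled with placental volume at other GAs; the fetal-side value is so
large that that barrier is effectively non-limiting and the maternal PStc
controls transfer. For cefazolin a specific PStc of 1 mL/s per mL tissue
multiplies the sub-tissue volume. An identifiability consequence, found
with the package's own fitting machinery: at the published maternal PStc
the barrier is close to flow-limited (PStc x fup exceeds the placental
plasma flow), so fetal plasma data constrain *decreases* of PStc much
better than increases. The parameter-recovery test therefore runs in the
permeability-limited regime (0.2x the published value) with a 12-point,
three-dose design.

# Numerics

The ODE system (16 states non-pregnant, 22 pregnant) is integrated with
`deSolve::lsoda` at relative tolerance 1e-8 and absolute tolerance 1e-10
µg, with solver restarts at every bolus time and infusion boundary. Mass
balance — compartment amounts plus urine sinks against administered
drug — is reported at every output time and stays at or below ~1e-9
relative in all packaged fixtures (the acceptance tolerance is 1e-6).
Tiny negative excursions within solver noise are clipped to zero in the
reported output. Degenerate one- and two-compartment graphs built with
`linear_graph()` run through the same solver and match closed-form and
matrix-exponential solutions to 0.1%, which is the regression guard on
the integrator configuration.

Parameter fitting minimizes the sum of squared log-concentration
residuals (fold errors penalized symmetrically) over the log of the free
multipliers with L-BFGS-B, and reports an identifiability diagnostic: the
objective increase under a 25% perturbation of each estimate, with a
warning when it is flat (as it is for OAT3 Vmax, which is shadowed by the
high passive basolateral permeability).

# Population simulation

Virtual subjects draw height and weight from a bivariate lognormal
(default correlation 0.5 — the source names the distribution but not its
parameters), age and GA uniform in their ranges, and lognormal
unit-mean multipliers for transporter Vmax (CV 100%, per kidney
protein-abundance variability) and GFR (CV 15%; 10-20% is the stated
default band where literature is silent). Simulations share a common
time grid; percentile bands (5/25/50/75/95) are computed pointwise and
are monotone by construction of the quantile call. Everything is
deterministic under a fixed seed. A delivery-sampling utility draws one
observation per subject to mimic cord-blood/amniotic-fluid sampling at
birth.

Problem sizes in the shipped tests were chosen for desk-scale runs: the
moment checks use 10,000 sampled multipliers, the reproducibility and
band-monotonicity checks use cohorts of 30-200 subjects over 6-hour
horizons, and the recovery experiments use 12-point schedules at three
dose levels.

# What the synthetic data do and do not show

The clinical profiles behind the original studies exist only as figures,
so the packaged validation rests on printed numbers (rate constants,
Km/fup/PStc values, urinary-excretion percentages), structural
invariants, and synthetic-data recovery via `synthesize_observed()`
(multiplicative lognormal noise on simulated truth). Passing these tests
shows the engine reproduces the published model's constants and
mechanics and that its estimator can recover parameters from data of the
stated design; it does not re-demonstrate agreement with the clinical
concentration-time points themselves. User-digitized CSVs can be overlaid
through the `observed_csv` slot of a scenario and scored with
`compute_fit_metrics()` (AAFE and fraction within two-fold, interpolating
predictions linearly in log concentration).

# Known limitations

* Oral/IM absorption, drug metabolism, saturable plasma-protein binding,
  fetal kidney transporters and a multi-organ fetus are out of scope, as
  in the source model.
* Cardiac output scales allometrically with current body weight; the
  larger hemodynamic rise of real pregnancy is not separately modeled.
* The 8-hour urinary-excretion ordering between pregnant and
  non-pregnant states holds for cefuroxime at 25 and 41 weeks and for
  cefazolin at 25 weeks, but reverses by ~1 percentage point for
  cefazolin at 41 weeks: its secretion-dominated clearance gains ~30%
  in pregnancy while the distribution volume (plasma expansion plus the
  fetal-amniotic reservoir) grows faster, fattening the late tail.
  Systemic clearance itself is higher in pregnancy for both drugs at all
  tested GAs.
* Fetal blood is treated as plasma-equivalent (no separate red-cell
  partitioning), and the fetal circulation is a single cardiac-output
  loop without a fetal lung.
* First-trimester predictions inherit the source model's caveat: the
  placental barrier parameters are calibrated at delivery and scaled by
  volume, so early-gestation fetal transfer should be treated as
  exploratory.
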