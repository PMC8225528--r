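## Maternal-fetal compartment graph assembly.
##
## The maternal whole-body model connects perfusion-limited tissues in
## parallel between arterial and venous plasma, with the lung in series.
## The kidney is permeability-limited: a perfused extracellular space, an
## intracellular space behind a passive basolateral PStc carrying OAT3
## influx, an MRP4 efflux step into the tubular filtrate, passive
## filtration (fup x GFR) into the filtrate, and drainage to a urine sink.
## During pregnancy the placenta splits into a maternal-facing perfused
## sub-tissue and a fetal-facing sub-tissue joined by the maternal-side
## PStc; the fetal side exchanges with fetal venous blood through the
## fetal-side PStc. The fetus is four compartments (arterial blood, venous
## blood, lumped tissue, fetal placenta) plus the amniotic fluid, coupled
## through the amniotic exchange pathways. All internal units: volumes mL,
## flows mL/h, amounts ug, concentrations ug/mL.

.PERFUSION_TISSUES <- c("heart", "spleen", "liver", "skin", "adipose",
                        "muscle", "brain", "rest", "uterus")

# PStc entry -> mL/h at the current sub-tissue volume (mL)
.pstc_mlh <- function(ps, volume_ml, ref_volume_ml = NULL) {
  if (identical(ps$units, "mL/s/mL")) {
    ps$value * volume_ml * .PSTC_MLS_TO_MLH
  } else {
    v <- ps$value * .PSTC_MLS_TO_MLH
    if (!is.null(ref_volume_ml) && ref_volume_ml > 0) {
      v <- v * volume_ml / ref_volume_ml   # scale absolute PStc with volume
    }
    v
  }
}

#' Build the maternal-fetal PBPK compartment graph
#'
#' Assembles all compartments, flows, permeability barriers, transporter
#' steps and amniotic pathways for a subject/drug pair at the subject's
#' gestational age. At GA = 0 the graph is the standard non-pregnant
#' whole-body model with no fetal or amniotic compartments.
#'
#' @param spec A [subject_spec()].
#' @param drug A [drug_parameters()] object.
#' @param amniotic_reference Optional override of the term reference
#'   amniotic rates (see [amniotic_rates()]).
#' @param postpartum_adjusted Apply the drug's postpartum MRP4 Vmax factor
#'   (used for postpartum/female model variants of compounds carrying one).
#' @param vmax_multipliers Optional named multipliers on transporter Vmax
#'   (names matching transporter names), used by population sampling.
#' @return An object of class `compartment_graph`.
#' @examples
#' cfx <- read_drug("cefuroxime")
#' g0 <- build_model(subject_spec(30, 70, 176, sex = "male"), cfx)
#' g41 <- build_model(subject_spec(30, 61.7, 163, gestational_age = 41), cfx)
#' @export
build_model <- function(spec, drug, amniotic_reference = NULL,
                        postpartum_adjusted = FALSE,
                        vmax_multipliers = NULL) {
  stopifnot(is_subject_spec(spec), inherits(drug, "drug_parameters"))
  ga <- spec$gestational_age
  phys <- maternal_physiology(spec)
  fet <- fetal_state(ga, fup = drug$fup)
  pregnant <- ga > 0

  tissues <- .PERFUSION_TISSUES
  if (spec$sex == "male") tissues <- setdiff(tissues, "uterus")

  # partition coefficients
  kp <- vapply(c(tissues, "lung"), function(t) {
    comp_name <- if (t == "rest") "rest" else t
    kp_lukacova(drug, comp_name)
  }, numeric(1))
  kp_ec_kidney <- kp_poulin_theil_extracellular(drug, "kidney")
  kp_ec_placenta <- kp_poulin_theil_extracellular(drug, "placenta")

  vol_ml <- phys$volumes * 1000
  q_mlh <- phys$plasma_flows * 1000
  pv_ml <- phys$plasma_volume * 1000
  gfr_mlh <- phys$gfr * .MLMIN_TO_MLH

  # transporters at current kidney size (expression constant per gram)
  kidney_ratio <- .preg_curves$kidney_ratio(ga)
  get_vmax <- function(tr) {
    v <- tr$vmax_ug_h * kidney_ratio
    if (!is.null(vmax_multipliers) && tr$name %in% names(vmax_multipliers)) {
      v <- v * vmax_multipliers[[tr$name]]
    }
    v
  }
  oat3 <- .get_transporter(drug, "OAT3")
  mrp4 <- .get_transporter(drug, "MRP4")
  mrp4_factor <- if (postpartum_adjusted) drug$mrp4_postpartum_factor else 1

  kidney_pstc <- drug$pstc$kidney
  if (is.null(kidney_pstc)) {
    abort("Drug demands a permeability-limited kidney but no kidney PStc is defined.")
  }

  p <- list(
    drug = drug$name,
    fup = drug$fup,
    mw = drug$molecular_weight,
    tissues = tissues,
    kp = kp,
    v_ven = 0.60 * pv_ml,
    v_art = 0.40 * pv_ml,
    v_lung = vol_ml[["lung"]],
    v_tis = vol_ml[tissues],
    q_tis = q_mlh[tissues],
    q_tot = sum(q_mlh[c(tissues, "kidney")],
                if (pregnant) q_mlh[["placenta"]] else 0),
    # kidney sub-structure: EC = vascular + interstitial (45% of organ),
    # IC = cells (55%), filtrate = tubular fluid (fixed 15 mL)
    v_kid_ec = 0.45 * vol_ml[["kidney"]],
    v_kid_ic = 0.55 * vol_ml[["kidney"]],
    v_filtrate = 15,
    q_kid = q_mlh[["kidney"]],
    kp_ec_kid = kp_ec_kidney,
    pstc_kid = .pstc_mlh(kidney_pstc, vol_ml[["kidney"]]),
    gfr = gfr_mlh,
    fu_ic = drug$fup,   # intracellular unbound fraction ~ plasma fup
    oat3_km = if (!is.null(oat3)) .km_ugml(oat3$km_uM, drug$molecular_weight) else NA,
    oat3_vmax = if (!is.null(oat3)) get_vmax(oat3) else 0,
    mrp4_km = if (!is.null(mrp4)) .km_ugml(mrp4$km_uM, drug$molecular_weight) else NA,
    mrp4_vmax = if (!is.null(mrp4)) get_vmax(mrp4) * mrp4_factor else 0,
    pregnant = pregnant
  )

  if (pregnant) {
    fup_f <- drug$fup_fetal %||% fet$fetal_fup
    kp_ft <- kp_lukacova(drug, "fetal_tissue")
    v_pl_mat <- vol_ml[["placenta"]]
    v_pl_fet <- fet$fetal_placenta_volume * 1000
    ps_perm <- identical(unname(drug$tissue_models[["placenta"]]), "permeability")

    # placental barriers
    pl_mat_entry <- drug$pstc$placenta_maternal %||% drug$pstc$placenta
    pl_fet_entry <- drug$pstc$placenta_fetal %||% drug$pstc$placenta
    ref_mat <- ref_fet <- NULL
    if (!is.null(pl_mat_entry$ga_ref)) {
      ref_mat <- .preg_curves$placenta_volume(pl_mat_entry$ga_ref) * 0.6 * 1000
    }
    if (!is.null(pl_fet_entry$ga_ref)) {
      ref_fet <- fetal_state(pl_fet_entry$ga_ref)$fetal_placenta_volume * 1000
    }

    fbv_ml <- fet$fetal_blood_volume * 1000
    q_fco <- 25.5 * fet$fetal_weight * (1 - fet$fetal_hematocrit) * 1000 # mL/h plasma
    rates <- amniotic_rates(ga, fet$fetal_weight,
                            reference = amniotic_reference %||% .amniotic_defaults)

    if (ps_perm) {
      pstc_mat <- .pstc_mlh(pl_mat_entry, v_pl_mat, ref_mat)
      pstc_fet <- .pstc_mlh(pl_fet_entry, v_pl_fet, ref_fet)
    } else {
      # perfusion (flow-limited) placenta: exchange limited by the smaller
      # of the maternal placental and fetal umbilical plasma flows
      pstc_mat <- pstc_fet <- min(q_mlh[["placenta"]], 0.4 * q_fco) * 10
    }

    p <- c(p, list(
      q_pl = q_mlh[["placenta"]],
      v_pl_mat = v_pl_mat,
      v_pl_fet = max(v_pl_fet, 1),
      kp_ec_pl = kp_ec_placenta,
      pstc_mat = pstc_mat,
      pstc_fet = pstc_fet,
      fup_f = fup_f,
      kp_ft = kp_ft,
      kp_uterus = kp[["uterus"]],
      v_f_art = 0.4 * fbv_ml,
      v_f_ven = 0.6 * fbv_ml,
      v_f_tis = fet$fetal_tissue_volume * 1000,
      v_af = max(fet$amniotic_fluid_volume * 1000, 1),
      q_fco = q_fco,
      cl_urine_f = fup_f * fet$fetal_gfr * .MLMIN_TO_MLH,  # mL/h
      k_sw = rates$k_sw * .LDAY_TO_MLH,
      k_sec = rates$k_sec * .LDAY_TO_MLH,
      k_intram = rates$k_intram * .LDAY_TO_MLH,
      k_trans = rates$k_trans * .LDAY_TO_MLH
    ))
  }

  state_names <- c("ven", "lung", "art", tissues,
                   "kid_ec", "kid_ic", "filtrate", "urine")
  if (pregnant) {
    state_names <- c(state_names, "placenta_mat", "placenta_fet",
                     "f_art", "f_ven", "f_tissue", "amniotic")
  }
  volumes <- c(ven = p$v_ven, lung = p$v_lung, art = p$v_art,
               setNames(p$v_tis, tissues),
               kid_ec = p$v_kid_ec, kid_ic = p$v_kid_ic,
               filtrate = p$v_filtrate, urine = NA)
  if (pregnant) {
    volumes <- c(volumes, placenta_mat = p$v_pl_mat,
                 placenta_fet = p$v_pl_fet, f_art = p$v_f_art,
                 f_ven = p$v_f_ven, f_tissue = p$v_f_tis,
                 amniotic = p$v_af)
  }

  n_tis <- length(tissues)
  structure(
    list(state_names = state_names, volumes = volumes, params = p,
         plasma_compartment = "ven",
         rhs = function(y, input_rate) .pbpk_rhs(y, p, n_tis, input_rate),
         subject = spec, drug = drug, physiology = phys, fetal = fet,
         rates = if (pregnant) amniotic_rates(ga, fet$fetal_weight,
            reference = amniotic_reference %||% .amniotic_defaults) else NULL),
    class = "compartment_graph"
  )
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat(sprintf("<compartment_graph> %s | %s | %d compartments%s\n",
              x$drug$name,
              if (x$params$pregnant)
                sprintf("GA %g wk", x$subject$gestational_age)
              else "non-pregnant",
              length(x$state_names),
              if (x$params$pregnant) " (incl. fetus + amniotic fluid)" else ""))
  invisible(x)
}

# Derivative function shared by all graphs. A is the amount vector (ug),
# input_rate the current IV infusion rate (ug/h) into maternal venous plasma.
.pbpk_rhs <- function(A, p, n_tis, input_rate) {
  ven <- A[[1L]]; lung <- A[[2L]]; art <- A[[3L]]
  tis <- A[4:(3 + n_tis)]
  kid_ec <- A[[4L + n_tis]]; kid_ic <- A[[5L + n_tis]]
  filt <- A[[6L + n_tis]]

  c_ven <- ven / p$v_ven
  c_lung <- lung / p$v_lung
  c_art <- art / p$v_art
  c_tis <- tis / p$v_tis
  c_kid_ec <- kid_ec / p$v_kid_ec
  c_kid_ic <- kid_ic / p$v_kid_ic
  c_filt <- filt / p$v_filtrate

  kp_t <- p$kp[p$tissues]
  out_tis <- p$q_tis * c_tis / kp_t
  d_tis <- p$q_tis * c_art - out_tis

  # kidney: plasma-referenced EC concentration, unbound driving forces
  c_kid_plasma <- c_kid_ec / p$kp_ec_kid
  cu_ec <- p$fup * c_kid_plasma
  cu_ic <- p$fu_ic * c_kid_ic
  j_pass <- p$pstc_kid * (cu_ec - cu_ic)
  j_oat3 <- if (p$oat3_vmax > 0) p$oat3_vmax * cu_ec / (p$oat3_km + cu_ec) else 0
  j_mrp4 <- if (p$mrp4_vmax > 0) p$mrp4_vmax * cu_ic / (p$mrp4_km + cu_ic) else 0
  j_filt <- p$fup * p$gfr * c_kid_plasma
  d_kid_ec <- p$q_kid * (c_art - c_kid_plasma) - j_pass - j_oat3 - j_filt
  d_kid_ic <- j_pass + j_oat3 - j_mrp4
  d_filt <- j_filt + j_mrp4 - p$gfr * c_filt
  d_urine <- p$gfr * c_filt

  venous_return <- sum(out_tis) + p$q_kid * c_kid_plasma
  art_out <- sum(p$q_tis) + p$q_kid

  if (p$pregnant) {
    pm <- A[[8L + n_tis]]; pf <- A[[9L + n_tis]]
    fa <- A[[10L + n_tis]]; fv <- A[[11L + n_tis]]
    ft <- A[[12L + n_tis]]; af <- A[[13L + n_tis]]
    c_pm <- pm / p$v_pl_mat; c_pf <- pf / p$v_pl_fet
    c_fa <- fa / p$v_f_art; c_fv <- fv / p$v_f_ven
    c_ft <- ft / p$v_f_tis; c_af <- af / p$v_af

    c_pm_plasma <- c_pm / p$kp_ec_pl
    cu_pm <- p$fup * c_pm_plasma
    cu_pf <- p$fup_f * c_pf / p$kp_ec_pl
    j_mat <- p$pstc_mat * (cu_pm - cu_pf)          # maternal barrier
    j_fet <- p$pstc_fet * (cu_pf - p$fup_f * c_fv) # fetal barrier -> venous
    d_pm <- p$q_pl * (c_art - c_pm_plasma) - j_mat
    venous_return <- venous_return + p$q_pl * c_pm_plasma
    art_out <- art_out + p$q_pl

    # amniotic pathways
    j_urine_f <- p$cl_urine_f * c_fa
    j_sw <- p$k_sw * c_af
    j_sec <- p$k_sec * c_ft
    j_intram <- p$k_intram * c_af
    iu <- match("uterus", p$tissues)
    cu_ut <- p$fup * c_tis[[iu]] / p$kp_uterus
    j_trans <- p$k_trans * (cu_ut - c_af)          # positive into amniotic
    d_tis[[iu]] <- d_tis[[iu]] - j_trans

    d_pf <- j_mat - j_fet
    d_fa <- p$q_fco * (c_fv - c_fa) - j_urine_f
    d_fv <- p$q_fco * (c_ft / p$kp_ft) - p$q_fco * c_fv + j_fet + j_intram
    d_ft <- p$q_fco * (c_fa - c_ft / p$kp_ft) + j_sw - j_sec
    d_af <- j_urine_f + j_sec + j_trans - j_sw - j_intram
    preg_d <- c(d_pm, d_pf, d_fa, d_fv, d_ft, d_af)
  } else {
    preg_d <- numeric(0)
  }

  d_ven <- venous_return - p$q_tot * c_ven + input_rate
  d_lung <- p$q_tot * (c_ven - c_lung / p$kp[["lung"]])
  d_art <- p$q_tot * c_lung / p$kp[["lung"]] - art_out * c_art

  c(d_ven, d_lung, d_art, d_tis, d_kid_ec, d_kid_ic, d_filt, d_urine, preg_d)
}
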