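# Cefuroxime (CFX): cephalosporin, 100% renally cleared unchanged
# (glomerular filtration + OAT3/MRP4 tubular secretion).
# Provenance tags: printed | supplementary | literature | fitted | assumed | calibrated
name: cefuroxime
molecular_weight: {value: 424.39, provenance: literature}
logP: {value: -0.16, provenance: literature}
pka:
  - {value: 2.45, type: acid, provenance: literature}
fup: {value: 0.67, provenance: literature}          # ~33% plasma protein bound
blood_plasma_ratio: {value: 0.55, provenance: literature}
# fetal fup derived at run time from the fetal albumin ratio
transporters:
  - name: OAT3
    location: kidney_basolateral
    direction: influx
    km_uM: {value: 300, provenance: assumed}        # high-affinity value unavailable; non-saturating per linear clinical PK
    vmax_ug_h: {value: 320000, provenance: fitted}  # fitted to baseline IV data
    vmax_cv: {value: 1.0, provenance: printed}      # 100% CV, population setting
  - name: MRP4
    location: kidney_apical
    direction: efflux
    km_uM: {value: 300, provenance: assumed}        # set equal to OAT3 (no data)
    vmax_ug_h: {value: 639000, provenance: fitted}
    vmax_cv: {value: 1.0, provenance: printed}
tissue_models:
  kidney: permeability
  placenta: permeability                            # switched after initial fetal overprediction
pstc:
  kidney:
    value: {value: 1.0, provenance: assumed}
    units: mL/s/mL
  placenta_maternal:
    value: {value: 15.9, provenance: printed}       # fitted in source study, printed value
    units: mL/s
    ga_ref: 41
  placenta_fetal:
    value: {value: 32400, provenance: printed}
    units: mL/s
    ga_ref: 41
mrp4_postpartum_factor: {value: 0.2, provenance: printed}  # five-fold Vmax reduction
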