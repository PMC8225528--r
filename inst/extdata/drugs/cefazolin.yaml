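# Cefazolin (CZ): cephalosporin, 100% renally cleared unchanged
# (glomerular filtration + OAT3/MRP4 tubular secretion).
# Provenance tags: printed | supplementary | literature | fitted | assumed | calibrated
name: cefazolin
molecular_weight: {value: 454.51, provenance: literature}
logP: {value: -0.58, provenance: literature}
pka:
  - {value: 2.30, type: acid, provenance: literature}
fup: {value: 0.09, provenance: printed}             # average compromise over the binding range
blood_plasma_ratio: {value: 0.55, provenance: assumed}
transporters:
  - name: OAT3
    location: kidney_basolateral
    direction: influx
    km_uM: {value: 117, provenance: printed}        # Ki from estrone-sulfate uptake inhibition
    vmax_ug_h: {value: 1700000, provenance: fitted}
    vmax_cv: {value: 1.0, provenance: printed}
  - name: MRP4
    location: kidney_apical
    direction: efflux
    km_uM: {value: 80.9, provenance: printed}       # membrane-vesicle Km
    vmax_ug_h: {value: 1574000, provenance: fitted}
    vmax_cv: {value: 1.0, provenance: printed}
tissue_models:
  kidney: permeability
  placenta: permeability
pstc:
  kidney:
    value: {value: 1.0, provenance: printed}        # specific PStc transferred from placenta fit
    units: mL/s/mL
  placenta:
    value: {value: 1.0, provenance: printed}        # specific value fitted to fetal Cp
    units: mL/s/mL
mrp4_postpartum_factor: {value: 1.0, provenance: printed}  # no postpartum adjustment needed
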