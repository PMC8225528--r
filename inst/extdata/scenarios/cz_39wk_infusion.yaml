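# 1 g IV infusion at 39 weeks gestation; publication omitted the infusion
# time and 30 min is assumed. Printed body weight (91 kg, typical at
# 39 GA) maps to ~78 kg pre-pregnancy under the weight-gain curve.
name: cz_39wk_infusion
drug: cefazolin
subject: {age: 31, weight: 78, height: 166, sex: female, gestational_age_weeks: 39}
regimen: {dose_mg: 1000, times_h: 0, duration_h: 0.5}
t_end_h: 12
dt_h: 0.1
notes: "infusion duration assumed (30 min); pre-pregnancy weight back-calculated"
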