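# 2 g IV bolus at 28 weeks gestation; printed 73 kg at 28 GA maps to
# ~65 kg pre-pregnancy under the weight-gain curve.
name: cz_28wk
drug: cefazolin
subject: {age: 30, weight: 65, height: 164, sex: female, gestational_age_weeks: 28}
regimen: {dose_mg: 2000, times_h: 0, duration_h: 0}
t_end_h: 12
dt_h: 0.1
notes: "pre-pregnancy weight back-calculated from printed on-study weight"
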