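# 0.5 g IV bolus at 25 weeks gestation, 25-year-old, 62 kg pre-pregnancy
# female (weight-gain curve supplies ~6 kg at this GA).
name: cz_25wk
drug: cefazolin
subject: {age: 25, weight: 62, height: 163, sex: female, gestational_age_weeks: 25}
regimen: {dose_mg: 500, times_h: 0, duration_h: 0}
t_end_h: 12
dt_h: 0.1
notes: "dose/route/demographics printed"
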