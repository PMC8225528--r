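# Baseline healthy-volunteer model development study: 1 g IV bolus,
# 32-year-old, 79 kg male.
name: cz_baseline_1g
drug: cefazolin
subject: {age: 32, weight: 79, height: 178, sex: male}
regimen: {dose_mg: 1000, times_h: 0, duration_h: 0}
t_end_h: 24
dt_h: 0.1
notes: "dose/route/demographics printed"
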