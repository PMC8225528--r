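# Baseline healthy-volunteer model development study: 1 g IV infused over
# 3 min in fasted 30-year-old, 70 kg male subjects.
name: cfx_baseline_1g
drug: cefuroxime
subject: {age: 30, weight: 70, height: 176, sex: male}
regimen: {dose_mg: 1000, times_h: 0, duration_h: 0.05}
t_end_h: 48
dt_h: 0.1
notes: "dose/route/demographics printed; sampling schedule configurable"
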