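# Delivery study: 0.75 g IV bolus at 41 weeks gestation; fetal plasma and
# amniotic fluid observables.
name: cfx_41wk
drug: cefuroxime
subject: {age: 30, weight: 61.7, height: 163, sex: female, gestational_age_weeks: 41}
regimen: {dose_mg: 750, times_h: 0, duration_h: 0}
t_end_h: 24
dt_h: 0.1
postpartum_adjusted: true
notes: "dose/route/demographics printed"
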