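scale,scale_type,item_id
physical_functioning,functional,q1
physical_functioning,functional,q2
physical_functioning,functional,q3
physical_functioning,functional,q4
physical_functioning,functional,q5
role_functioning,functional,q6
role_functioning,functional,q7
emotional_functioning,functional,q21
emotional_functioning,functional,q22
emotional_functioning,functional,q23
emotional_functioning,functional,q24
cognitive_functioning,functional,q20
cognitive_functioning,functional,q25
social_functioning,functional,q26
social_functioning,functional,q27
fatigue,symptom,q10
fatigue,symptom,q12
fatigue,symptom,q18
nausea_vomiting,symptom,q14
nausea_vomiting,symptom,q15
pain,symptom,q9
pain,symptom,q19
dyspnoea,symptom,q8
insomnia,symptom,q11
appetite_loss,symptom,q13
constipation,symptom,q16
diarrhoea,symptom,q17
financial_difficulties,symptom,q28
global_health,global,q29
global_health,global,q30
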