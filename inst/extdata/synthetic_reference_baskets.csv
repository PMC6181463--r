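state,resource,category,unit_price_clp,monthly_quantity,user_fraction
mild,gp_visit,medical_visit,13000,1,0.8
mild,oral_analgesics,pharmacological,3500,1,1
mild,physio_session,physiotherapy,13926.53125,2,0.4
moderate,gp_visit,medical_visit,13000,1,0.9
moderate,specialist_visit,medical_visit,22000,0.5,0.35
moderate,combination_analgesics,pharmacological,6500,1,1
moderate,physio_session,physiotherapy,13409.42,3,0.45
severe,emergency_visit,medical_visit,42000,1,0.9
severe,specialist_visit,medical_visit,22000,1,0.6
severe,opioid_regimen,pharmacological,18000,1,0.85
severe,physio_session,physiotherapy,14000,4,0.55
severe,hospital_admission,hospitalization,1604583.9583333333,1,0.12
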