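# Published prevalence aggregates for six adult health indicators in New
# York City: the gold-standard examination survey (NYC HANES 2013-14,
# n = 1135) and the post-stratified EHR-based surveillance system (NYC
# Macroscope 2013, n = 716076). Estimates and 95% CIs are the printed
# values, as decimals. Label suffix _survey = NYC HANES, _ehr =
# post-stratified NYC Macroscope.
label,p_hat,ci_lower,ci_upper,n
hypertension_survey,0.343,0.313,0.374,1135
hypertension_ehr,0.347,0.346,0.348,716076
diabetes_survey,0.133,0.113,0.156,1135
diabetes_ehr,0.149,0.149,0.150,716076
smoking_survey,0.173,0.151,0.199,1135
smoking_ehr,0.150,0.149,0.151,716076
obesity_survey,0.317,0.287,0.348,1135
obesity_ehr,0.280,0.279,0.281,716076
depression_survey,0.190,0.166,0.216,1135
depression_ehr,0.083,0.083,0.084,716076
influenza_survey,0.486,0.454,0.518,1135
influenza_ehr,0.217,0.216,0.218,716076
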