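# Depression rows from the packaged NYC aggregates, in the two-row layout
# expected by the `pool` command (survey first, record source second).
label,p_hat,ci_lower,ci_upper,n
depression_survey,0.190,0.166,0.216,1135
depression_ehr,0.083,0.083,0.084,716076
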