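session_id,family_id,caregiver_id,caregiver_role,infant_id,infant_sex,pnd,rearing,assay,nominal_duration
S1,F1,M1,mother,I1,f,10,family,retrieval,300
S2,F1,M1,mother,I1,f,17,family,retrieval,300
S3,F1,M2,father,I1,f,10,family,retrieval,300
S4,F1,M2,father,I1,f,17,family,retrieval,300
S5,F1,M1,mother,I2,m,12,family,retrieval,300
S6,F1,M2,father,I2,m,30,family,retrieval,300
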