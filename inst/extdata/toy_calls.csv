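session_id,caller,call_type,onset_s,offset_s
S1,infant,phee,5,5.4
S1,infant,twitter,12,12.8
S1,infant,trill,60,60.5
S1,infant,tsik,100.6,100.9
S1,infant,cry,105,105.6
S1,caregiver,twitter,31,31.9
S3,infant,trill,100,100.4
S3,infant,trill,150,150.5
S3,caregiver,phee,50,50.9
S3,unclear,twitter,70,70.7
S4,infant,cry,64,64.8
S4,infant,trill,160,160.4
S5,infant,tsik,100.5,100.8
S5,infant,trill,200,200.3
S6,infant,phee,5,5.5
S6,infant,cry,205,205.7
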