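session_id,actor,behavior,onset_s,offset_s
S1,infant,in_basket,0,30
S1,caregiver,retrieval,30,30.2
S1,caregiver,carry_contact,30,103
S1,caregiver,locomotion,30,50
S1,caregiver,rejection,100,102
S1,infant,dismount,103,103.2
S1,caregiver,contact,150,153
S1,caregiver,retrieval,200,200.2
S1,caregiver,carry_contact,200,330
S2,infant,in_basket,0,300
S3,infant,in_basket,0,10
S3,caregiver,retrieval,10,10.2
S3,caregiver,carry_contact,10,310
S3,caregiver,locomotion,60,80
S4,infant,in_basket,0,20
S4,caregiver,retrieval,20,20.2
S4,caregiver,carry_contact,20,63
S4,caregiver,rejection,60,61
S4,infant,dismount,63,63.2
S4,caregiver,contact,120,122
S4,infant,cling,120,120.4
S4,caregiver,retrieval,150,150.2
S4,caregiver,carry_contact,150,320
S5,infant,in_basket,0,40
S5,caregiver,retrieval,40,40.2
S5,caregiver,carry_contact,40,340
S5,caregiver,rejection,100,101
S6,infant,in_basket,0,15
S6,caregiver,retrieval,15,15.2
S6,caregiver,carry_contact,15,200
S6,infant,dismount,200,200.2
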