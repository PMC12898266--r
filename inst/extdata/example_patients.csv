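patient_id,age,charl_2yr,charl_ever,elix_2yr,elix_ever,index_date,death60
P1,67,2,3,1,2,2015-02-14,0
P2,58,1,1,0,1,2015-08-03,0
P3,74,4,5,3,4,2015-03-06,1
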