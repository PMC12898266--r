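patient_id,cm_name,date,value
P1,SBP,2015-01-01,130
P1,SBP,2015-01-11,150
P1,SBP,2015-01-21,160
P1,SBP,2015-01-31,135
P1,SBP,2015-02-05,170
P2,A1c,2015-01-01,6.5
P2,A1c,2015-04-11,7.5
P2,A1c,2015-07-20,7.2
P2,height,2015-01-01,1.75
P2,weight,2015-05-01,77.175
P3,O2Sat,2015-01-01,93
P3,eGFR,2015-01-01,55
P3,eGFR,2015-02-20,65
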