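# Default treatment targets (editable): a value is abnormal when strictly
# below `low` or strictly above `high`. Units: SBP/DBP mmHg, O2Sat %, BMI
# kg/m2, eGFR mL/min/1.73m2, Alb g/dL (serum albumin), HCT %, ALT U/L,
# A1c %, HDL/LDL mg/dL.
SBP:
  high: 140
DBP:
  high: 90
O2Sat:
  low: 95
BMI:
  high: 30
eGFR:
  low: 60
Alb:
  low: 3.5
HCT:
  low: 38
  high: 52
ALT:
  high: 40
A1c:
  high: 7
HDL:
  low: 40
LDL:
  high: 130
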