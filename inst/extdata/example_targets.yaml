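# Targets for the packaged 3-patient example (subset of the defaults).
SBP:
  high: 140
A1c:
  high: 7
O2Sat:
  low: 95
eGFR:
  low: 60
BMI:
  high: 30
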