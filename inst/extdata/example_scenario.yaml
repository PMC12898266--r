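# Example scenario override: start from the default scenario, raise the
# per-measurement missingness and slow the visit process.
missing_cm_prob: 0.05
visit:
  base_rate: 1.2
  abnormal_mult: 3
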