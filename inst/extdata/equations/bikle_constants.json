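{
  "ka_dbp": 800000000,
  "ka_alb": 600000,
  "mw_25ohd": 400.64,
  "mw_vdbp": 58000,
  "mw_albumin": 66430
}
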