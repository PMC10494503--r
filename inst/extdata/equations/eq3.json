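{
  "name": "eq3",
  "intercept": 3.098,
  "terms": [
    {
      "variable": "albumin",
      "transform": "identity",
      "coefficient": 0.275
    },
    {
      "variable": "d25_3",
      "transform": "log",
      "coefficient": 2.37
    },
    {
      "variable": "ipth",
      "transform": "log",
      "coefficient": -0.467
    },
    {
      "variable": "d1_25_3",
      "transform": "log",
      "coefficient": -1.194
    }
  ]
}
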