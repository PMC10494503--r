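{
  "name": "eq1",
  "intercept": 12.202,
  "terms": [
    {
      "variable": "albumin",
      "transform": "identity",
      "coefficient": 0.359
    },
    {
      "variable": "d25_3",
      "transform": "log",
      "coefficient": 0.844
    },
    {
      "variable": "d25_2",
      "transform": "log",
      "coefficient": 0.145
    },
    {
      "variable": "vdbp",
      "transform": "log",
      "coefficient": -1.522
    },
    {
      "variable": "d1_25_3",
      "transform": "log",
      "coefficient": -0.851
    },
    {
      "variable": "d24_25_3",
      "transform": "log",
      "coefficient": -1.906
    }
  ],
  "interactions": [
    {
      "var_a": "d25_3",
      "var_b": "d24_25_3",
      "coefficient": 0.943
    }
  ]
}
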