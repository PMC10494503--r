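{
  "name": "eq2",
  "intercept": 12.779,
  "terms": [
    {
      "variable": "albumin",
      "transform": "identity",
      "coefficient": 0.348
    },
    {
      "variable": "d25_3",
      "transform": "log",
      "coefficient": 0.748
    },
    {
      "variable": "vdbp",
      "transform": "log",
      "coefficient": -1.566
    },
    {
      "variable": "d25_2",
      "transform": "log",
      "coefficient": 0.149
    },
    {
      "variable": "d1_25_3",
      "transform": "log",
      "coefficient": -0.833
    },
    {
      "variable": "d24_25_3",
      "transform": "log",
      "coefficient": -1.826
    }
  ],
  "interactions": [
    {
      "var_a": "d25_3",
      "var_b": "d24_25_3",
      "coefficient": 0.935
    }
  ],
  "phenotype_offsets": {
    "Gc1f/Gc1f": 0,
    "Gc1f/Gc1s": 0.019716,
    "Gc1s/Gc1s": 0.002741,
    "Gc2/Gc1f": -0.394562,
    "Gc2/Gc1s": -0.1283514,
    "Gc2/Gc2": -0.1381116
  }
}
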