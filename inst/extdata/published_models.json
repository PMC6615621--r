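{
  "comment": "Published coefficient constants for the built-in models, kept as an independent literal copy so code constants can be cross-checked digit for digit.",
  "d1": {
    "intercept": -9.59,
    "hr": 2.39,
    "age": 0.274,
    "sex": -0.204,
    "fvc": 0.52
  },
  "d2": {
    "intercept": -8.57,
    "hr": 1.72,
    "fb": 0.611,
    "age": 0.298,
    "sex": -0.206,
    "fvc": 0.614
  },
  "legacy": {
    "zuurbier": {"male": {"a": 1.03, "b": 0.021}, "female": {"a": 0.57, "b": 0.023}},
    "ramos": {"male": {"a": 1.17, "b": 0.02}, "female": {"a": 0.99, "b": 0.02}},
    "cozza": {"a": 0.58, "b": 0.025},
    "do_vale": {"a": 0.00071, "b": 2.17},
    "mcardle": {"a": 1.8028, "b": 3.8881},
    "greenwald2014": {"a": -4.247, "b_hr": 0.0595, "b_fb": 0.226}
  }
}
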