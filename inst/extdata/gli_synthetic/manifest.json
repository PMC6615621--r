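{
  "source": "synthetic reference table generated by the ventdose authors",
  "note": "GLI functional form, synthetic coefficients calibrated to physiologic adult FVC (about 5.5 L male / 3.8 L female at reference height and age 30) with FEV1 = 0.8 FVC; not a published equation set",
  "version": "0.1.0"
}
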