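{
  "comment": "Synthetic linear score-to-utility mapping fixture (not a published tariff). utility = intercept + slope * score, clamped to bounds.",
  "intercept": 0.13,
  "slope": 0.01,
  "bounds": [0, 1],
  "mae": 0.0946,
  "score_range": [0, 100]
}
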