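{
  "n": 2000,
  "seed": 20211022,
  "progression": {"treatment_effect": 0.25, "annual_discontinuation": 0.10},
  "pricing": {"annual_price": 16000, "one_time_prices": [100000, 250000], "effect_scales": [1, 2]}
}
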