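[
  {
    "label": "cnt_3_1",
    "n": 3,
    "m": 1,
    "m_eff_ratio": 0.507,
    "default_tau_s": 1e-13,
    "default_temperature_K": 310
  },
  {
    "label": "cnt_7_3",
    "n": 7,
    "m": 3,
    "m_eff_ratio": 0.116,
    "default_tau_s": 1e-13,
    "default_temperature_K": 310
  }
]
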