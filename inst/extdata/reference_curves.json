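[
  {"compound_id": "gallic_acid", "slope": 6411.2, "intercept": -13176, "r": 0.9999, "range": [3.89, 124.44]},
  {"compound_id": "hmf", "slope": 7856, "intercept": -7229, "r": 0.9999, "range": [3.75, 120.12]},
  {"compound_id": "morroniside", "slope": 14534, "intercept": -64815, "r": 0.9999, "range": [22.51, 720.30]},
  {"compound_id": "cornin", "slope": 10795, "intercept": -3398.3, "r": 0.9995, "range": [0.71, 22.74]},
  {"compound_id": "sweroside", "slope": 13446, "intercept": -7742.1, "r": 0.9998, "range": [1.90, 60.66]},
  {"compound_id": "loganin", "slope": 14317, "intercept": -32209, "r": 0.9999, "range": [12.97, 415.20]},
  {"compound_id": "methylmorroniside_7a", "slope": 12640, "intercept": -3224.1, "r": 0.9999, "range": [1.26, 40.20]},
  {"compound_id": "methylmorroniside_7b", "slope": 15128, "intercept": -9720.8, "r": 0.9998, "range": [2.55, 81.52]},
  {"compound_id": "ethylmorroniside_7a", "slope": 14273, "intercept": -283.77, "r": 0.9999, "range": [0.63, 20.16]},
  {"compound_id": "ethylmorroniside_7b", "slope": 12527, "intercept": -1411.6, "r": 0.9998, "range": [0.63, 20.12]},
  {"compound_id": "cornuside", "slope": 12461, "intercept": -11069, "r": 0.9999, "range": [3.39, 108.64]}
]
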