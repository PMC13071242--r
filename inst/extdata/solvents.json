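[
  {"name": "acetone",       "epsilon": 20.7, "aliases": ["acetone-d6", "(CD3)2CO"]},
  {"name": "chloroform",    "epsilon": 4.8,  "aliases": ["CDCl3", "CHCl3", "chloroform-d"]},
  {"name": "DMSO",          "epsilon": 46.7, "aliases": ["DMSO-d6", "dimethyl sulfoxide", "dimethylsulfoxide"]},
  {"name": "MeOH",          "epsilon": 32.7, "aliases": ["MeOH-d4", "methanol", "methanol-d4", "CD3OD"]},
  {"name": "THF",           "epsilon": 7.6,  "aliases": ["THF-d8", "tetrahydrofuran"]},
  {"name": "acetonitrile",  "epsilon": 37.5, "aliases": ["ACN", "ACN-d3", "CD3CN", "MeCN"]},
  {"name": "water",         "epsilon": 78.5, "aliases": ["D2O", "H2O", "deuterium oxide"]}
]
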