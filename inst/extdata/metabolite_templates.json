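[
  {
    "name": "lactate",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 1.310, "relative_area": 0.375, "linewidth": 0.0035},
      {"center": 1.322, "relative_area": 0.375, "linewidth": 0.0040},
      {"center": 4.082, "relative_area": 0.03125, "linewidth": 0.0040},
      {"center": 4.094, "relative_area": 0.09375, "linewidth": 0.0040},
      {"center": 4.106, "relative_area": 0.09375, "linewidth": 0.0040},
      {"center": 4.118, "relative_area": 0.03125, "linewidth": 0.0040}
    ]
  },
  {
    "name": "creatine",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 3.030, "relative_area": 0.6, "linewidth": 0.0035},
      {"center": 3.930, "relative_area": 0.4, "linewidth": 0.0035}
    ]
  },
  {
    "name": "glycine",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 3.548, "relative_area": 1.0, "linewidth": 0.0035}
    ]
  },
  {
    "name": "choline",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 3.185, "relative_area": 0.82, "linewidth": 0.0035},
      {"center": 3.501, "relative_area": 0.09, "linewidth": 0.0040},
      {"center": 4.056, "relative_area": 0.09, "linewidth": 0.0040}
    ]
  },
  {
    "name": "phosphocholine",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 3.208, "relative_area": 0.82, "linewidth": 0.0035},
      {"center": 3.584, "relative_area": 0.09, "linewidth": 0.0040},
      {"center": 4.162, "relative_area": 0.09, "linewidth": 0.0040}
    ]
  },
  {
    "name": "myo-inositol",
    "lineshape": "lorentzian",
    "peaks": [
      {"center": 3.268, "relative_area": 0.167, "linewidth": 0.0040},
      {"center": 3.522, "relative_area": 0.333, "linewidth": 0.0040},
      {"center": 3.612, "relative_area": 0.333, "linewidth": 0.0040},
      {"center": 4.052, "relative_area": 0.167, "linewidth": 0.0040}
    ]
  }
]
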