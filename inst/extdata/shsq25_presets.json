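{
  "instrument": "SHSQ-25",
  "scale": [0, 4],
  "items": ["CS1", "CS2", "CS3", "DS1", "DS2", "DS3",
            "FT1", "FT2", "FT3", "FT4", "FT5", "FT6", "FT7", "FT8", "FT9",
            "IS1", "IS2", "IS3",
            "MH1", "MH2", "MH3", "MH4", "MH5", "MH6", "MH7"],
  "domains": ["CS", "CS", "CS", "DS", "DS", "DS",
              "FT", "FT", "FT", "FT", "FT", "FT", "FT", "FT", "FT",
              "IS", "IS", "IS",
              "MH", "MH", "MH", "MH", "MH", "MH", "MH"],
  "optimal_like": {
    "n": 106,
    "mean": [0.11, 0.10, 0.37, 0.14, 0.28, 0.23,
             0.64, 0.34, 0.34, 0.75, 0.28, 0.37, 1.02, 0.79, 0.42,
             0.15, 0.51, 0.22,
             0.39, 0.29, 1.15, 0.42, 0.43, 0.33, 0.34],
    "sd":   [0.37, 0.36, 0.81, 0.52, 0.77, 0.63,
             1.01, 0.59, 0.65, 0.96, 0.58, 0.72, 1.15, 1.03, 0.77,
             0.39, 0.81, 0.57,
             0.85, 0.65, 1.21, 0.63, 0.76, 0.69, 0.80]
  },
  "suboptimal_like": {
    "n": 111,
    "mean": [0.94, 1.13, 1.59, 0.75, 1.23, 0.96,
             2.20, 1.32, 1.26, 2.14, 1.52, 1.58, 2.10, 2.14, 1.60,
             1.15, 1.43, 1.17,
             0.98, 1.19, 2.07, 1.14, 1.17, 1.06, 1.37],
    "sd":   [0.85, 1.10, 1.23, 0.97, 1.15, 1.04,
             1.07, 0.95, 0.91, 1.28, 1.24, 1.17, 1.03, 0.90, 1.22,
             0.96, 1.10, 1.17,
             1.14, 1.11, 1.25, 0.89, 0.99, 1.02, 1.30]
  }
}
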