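{
  "description": "Published group-level summary statistics (mean, SD, n per stratum) for the demographic and anthropometric variables of the SHSQ-25 validation cohort, with the printed effect-size labels. Used to recompute effect sizes and tests from summaries; not respondent-level data.",
  "groups": {"optimal": 106, "suboptimal": 111},
  "numeric": [
    {"variable": "age",   "optimal_mean": 53.09, "optimal_sd": 7.57,  "suboptimal_mean": 57.02, "suboptimal_sd": 10.43, "printed_d": 0.43,  "printed_label": "medium", "printed_p": 0.002},
    {"variable": "bmi",   "optimal_mean": 25.67, "optimal_sd": 4.78,  "suboptimal_mean": 25.56, "suboptimal_sd": 5.04,  "printed_d": 0.02,  "printed_label": "small",  "printed_p": 0.869},
    {"variable": "sbp",   "optimal_mean": 142.06, "optimal_sd": 22.86, "suboptimal_mean": 149.70, "suboptimal_sd": 25.31, "printed_d": 0.32, "printed_label": "small",  "printed_p": 0.021},
    {"variable": "dbp",   "optimal_mean": 82.52, "optimal_sd": 12.99, "suboptimal_mean": 86.58, "suboptimal_sd": 15.54, "printed_d": 0.28,  "printed_label": "small",  "printed_p": 0.038},
    {"variable": "height", "optimal_mean": 1.64, "optimal_sd": 0.07,  "suboptimal_mean": 1.61, "suboptimal_sd": 0.07,   "printed_d": 0.03,  "printed_label": "small",  "printed_p": 0.837},
    {"variable": "weight", "optimal_mean": 68.70, "optimal_sd": 12.78, "suboptimal_mean": 66.49, "suboptimal_sd": 14.40, "printed_d": 0.16, "printed_label": "small",  "printed_p": 0.234},
    {"variable": "waist",  "optimal_mean": 89.72, "optimal_sd": 12.57, "suboptimal_mean": 90.86, "suboptimal_sd": 12.95, "printed_d": 0.09, "printed_label": "small",  "printed_p": 0.512},
    {"variable": "hip",    "optimal_mean": 101.22, "optimal_sd": 10.82, "suboptimal_mean": 101.20, "suboptimal_sd": 10.91, "printed_d": 0.002, "printed_label": "small", "printed_p": 0.989},
    {"variable": "whtr",   "optimal_mean": 0.55, "optimal_sd": 0.08,  "suboptimal_mean": 0.56, "suboptimal_sd": 0.08,   "printed_d": 0.13,  "printed_label": "small",  "printed_p": 0.358}
  ],
  "categorical": [
    {"variable": "gender", "levels": ["female", "male"], "optimal": [59, 47], "suboptimal": [74, 37]}
  ]
}
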