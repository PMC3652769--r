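{
  "comment": "Published reference values for the minimisation simulation study this package reproduces. cutoff_schedule: small-trial imbalance cutoffs (exact). steady_state: pooled tie/deterministic percentages at P=1 for arms x binary-factor combinations, read in the large-trial regime (stochastic, tolerance +/-3 percentage points). pscan_reference: a P-scan summary row. max_reduction: maximum achievable decrease in predictability (percentage-point range) by arms x number of variables.",
  "cutoff_schedule": [
    {"n": 10, "cutoff_percent": 40, "ratio": "7:3"},
    {"n": 20, "cutoff_percent": 20, "ratio": "12:8"},
    {"n": 30, "cutoff_percent": 10, "ratio": "17:13"},
    {"n": 40, "cutoff_percent": 10, "ratio": "22:18"},
    {"n": 50, "cutoff_percent": 5, "ratio": "27:23"}
  ],
  "steady_state": [
    {"arms": 2, "n_binary_factors": 1, "tie_pct": 50, "deterministic_pct": 50, "tolerance_pct": 3},
    {"arms": 2, "n_binary_factors": 2, "tie_pct": 28, "deterministic_pct": 72, "tolerance_pct": 3},
    {"arms": 2, "n_binary_factors": 3, "tie_pct": 20, "deterministic_pct": 80, "tolerance_pct": 3},
    {"arms": 2, "n_binary_factors": 4, "tie_pct": 15, "deterministic_pct": 85, "tolerance_pct": 3},
    {"arms": 3, "n_binary_factors": 1, "tie_pct": 67, "deterministic_pct": 33, "tolerance_pct": 3},
    {"arms": 3, "n_binary_factors": 2, "tie_pct": 44, "deterministic_pct": 56, "tolerance_pct": 3},
    {"arms": 3, "n_binary_factors": 3, "tie_pct": 33, "deterministic_pct": 67, "tolerance_pct": 3},
    {"arms": 3, "n_binary_factors": 4, "tie_pct": 26, "deterministic_pct": 74, "tolerance_pct": 3},
    {"arms": 4, "n_binary_factors": 1, "tie_pct": 76, "deterministic_pct": 24, "tolerance_pct": 3},
    {"arms": 4, "n_binary_factors": 2, "tie_pct": 55, "deterministic_pct": 45, "tolerance_pct": 3},
    {"arms": 4, "n_binary_factors": 3, "tie_pct": 42, "deterministic_pct": 58, "tolerance_pct": 3},
    {"arms": 4, "n_binary_factors": 4, "tie_pct": 33, "deterministic_pct": 67, "tolerance_pct": 3}
  ],
  "pscan_reference": [
    {"arms": 2, "n_binary_factors": 3, "n": 300, "recommended_p": 0.7,
     "predictability_at_recommended": 63.0, "reduction_pct": 17.0,
     "onset_p": 0.6, "tolerance_pct": 3}
  ],
  "max_reduction": [
    {"arms": 2, "n_variables": 1, "min_pct": 0, "max_pct": 1},
    {"arms": 2, "n_variables": 2, "min_pct": 4, "max_pct": 12},
    {"arms": 2, "n_variables": 3, "min_pct": 6, "max_pct": 17},
    {"arms": 2, "n_variables": 4, "min_pct": 7, "max_pct": 20},
    {"arms": 3, "n_variables": 1, "min_pct": 0, "max_pct": 1},
    {"arms": 3, "n_variables": 2, "min_pct": 2, "max_pct": 8},
    {"arms": 3, "n_variables": 3, "min_pct": 11, "max_pct": 12},
    {"arms": 3, "n_variables": 4, "min_pct": 10, "max_pct": 17},
    {"arms": 4, "n_variables": 1, "min_pct": 0, "max_pct": 1},
    {"arms": 4, "n_variables": 2, "min_pct": 0, "max_pct": 4},
    {"arms": 4, "n_variables": 3, "min_pct": 0, "max_pct": 9},
    {"arms": 4, "n_variables": 4, "min_pct": 8, "max_pct": 14}
  ]
}
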