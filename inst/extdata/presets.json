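{
  "ic50_human": {
    "kind": "dose_response",
    "description": "NF-Y reporter inhibition in human cardiac fibroblasts",
    "ic50_truth": 19.95,
    "hill": 1.0,
    "top": 1.0,
    "bottom": 0.0,
    "doses": [0, 2.5, 5, 10, 20, 30],
    "replicates": 4,
    "noise_cv": 0.10,
    "seed": 101
  },
  "ic50_rat": {
    "kind": "dose_response",
    "description": "NF-Y reporter inhibition in rat cardiac fibroblasts",
    "ic50_truth": 12.73,
    "hill": 1.0,
    "top": 1.0,
    "bottom": 0.0,
    "doses": [0, 2.5, 5, 10, 20, 30],
    "replicates": 4,
    "noise_cv": 0.10,
    "seed": 102
  },
  "chase_nfya_control": {
    "kind": "chase",
    "description": "endogenous NF-YA, vehicle control",
    "t_half_truth": 16.5,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 201
  },
  "chase_nfya_treated": {
    "kind": "chase",
    "description": "endogenous NF-YA, 20 uM inhibitor",
    "t_half_truth": 8.5,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 202
  },
  "chase_flag_wt": {
    "kind": "chase",
    "description": "exogenous FLAG-tagged wild-type NF-YA, untreated",
    "t_half_truth": 8.8,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 203
  },
  "chase_flag_wt_treated": {
    "kind": "chase",
    "description": "exogenous FLAG-tagged wild-type NF-YA, inhibitor-treated",
    "t_half_truth": 6.2,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 204
  },
  "chase_flag_6ktor": {
    "kind": "chase",
    "description": "exogenous FLAG-tagged lysine-free (6KtoR) NF-YA, untreated",
    "t_half_truth": 8.1,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 205
  },
  "chase_flag_6ktor_treated": {
    "kind": "chase",
    "description": "exogenous FLAG-tagged lysine-free (6KtoR) NF-YA, inhibitor-treated",
    "t_half_truth": 5.7,
    "timepoints": [0, 4, 8, 16, 24],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 206
  },
  "chase_nfya_control_short": {
    "kind": "chase",
    "description": "endogenous NF-YA control, two-point 8 h chase design",
    "t_half_truth": 16.5,
    "timepoints": [0, 8],
    "replicates": 4,
    "noise_cv": 0.05,
    "seed": 207
  },
  "rmsf_contrast": {
    "kind": "trajectory",
    "description": "high/low flexibility contrast: per-coordinate jitter sd in Angstrom",
    "amplitude_high": 0.9,
    "amplitude_low": 0.3,
    "n_frames": 5000,
    "seed": 301
  }
}
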