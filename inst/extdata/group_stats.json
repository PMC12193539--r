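{
  "_note": [
    "Printed group-comparison statistics from the published study narrative.",
    "Counts are not printed; they are reconstructed from percentage x n via",
    "counts_from_percent(). The printed guarding-duration t = 0.8 is",
    "internally inconsistent with its own df = 39 and p = 0.02; the",
    "recomputed statistic is the tested value."
  ],
  "n_trials": {"virgin": 26, "once_mated": 15},
  "proportions": [
    {
      "label": "males_walking_at_start",
      "virgin_percent": 84.6, "virgin_n": 26,
      "mated_percent": 53.0, "mated_n": 15,
      "printed_z": 1.8, "printed_p": 0.061
    },
    {
      "label": "males_showing_MHAM",
      "virgin_percent": 34.0, "virgin_n": 26,
      "mated_percent": 26.0, "mated_n": 15,
      "printed_z": 0.18, "printed_p": 0.85
    }
  ],
  "durations": [
    {
      "label": "male_guarding_seconds",
      "virgin": {"mean": 387.5, "sem": 46.8, "n": 26},
      "mated": {"mean": 219.0, "sem": 52.0, "n": 15},
      "printed_t": 0.8, "printed_df": 39, "printed_p": 0.02
    }
  ],
  "female_duration_tests": [
    {"label": "FWK_seconds", "printed_t": 0.83, "printed_df": 39, "printed_p": 0.4},
    {"label": "FM_seconds", "printed_t": 1.5, "printed_df": 39, "printed_p": 0.14},
    {"label": "FQHM_seconds", "printed_t": 0.67, "printed_df": 39, "printed_p": 0.5}
  ]
}
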