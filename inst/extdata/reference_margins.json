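{
  "_note": [
    "Printed row/column margins, grand totals and omnibus statistics of the",
    "published transition tables. The virgin_female column header printed",
    "'FHC' in the source; normalized to the repertoire code FHMCA. The",
    "mated_female antecedent list includes the terminal act FWP as a",
    "structural zero row: the printed omnibus df (49) corresponds to an 8x8",
    "grid, while only 7 antecedent rows carry entries."
  ],
  "virgin_male": {
    "sex": "male",
    "n_trials": 26,
    "antecedents": ["MW", "MHAM", "MTDF", "MWDF", "MATFB", "MHFAR", "MEE", "MIE", "MM", "MG"],
    "subsequents": ["MW", "MHAM", "MTDF", "MWDF", "MATFB", "MHFAR", "MEE", "MIE", "MM", "MG", "MWP"],
    "row_totals": {"MW": 29, "MHAM": 13, "MTDF": 30, "MWDF": 30, "MATFB": 34, "MHFAR": 36, "MEE": 27, "MIE": 27, "MM": 27, "MG": 5},
    "col_totals": {"MW": 14, "MHAM": 9, "MTDF": 28, "MWDF": 30, "MATFB": 30, "MHFAR": 34, "MEE": 27, "MIE": 27, "MM": 27, "MG": 27, "MWP": 5},
    "grand_total": 258,
    "sum_chi_sq": 1646.4,
    "df": 90
  },
  "mated_male": {
    "sex": "male",
    "n_trials": 15,
    "antecedents": ["MQ", "MW", "MHAM", "MTDF", "MWDF", "MATFB", "MHFAR", "MEE", "MIE", "MM", "MG"],
    "subsequents": ["MQ", "MW", "MHAM", "MTDF", "MWDF", "MATFB", "MHFAR", "MEE", "MIE", "MM", "MG", "MWP", "MQP"],
    "row_totals": {"MQ": 12, "MW": 26, "MHAM": 4, "MTDF": 14, "MWDF": 14, "MATFB": 10, "MHFAR": 18, "MEE": 14, "MIE": 14, "MM": 14, "MG": 9},
    "col_totals": {"MQ": 7, "MW": 12, "MHAM": 8, "MTDF": 14, "MWDF": 14, "MATFB": 19, "MHFAR": 10, "MEE": 14, "MIE": 14, "MM": 14, "MG": 14, "MWP": 5, "MQP": 4},
    "grand_total": 149,
    "sum_chi_sq": 1093.5,
    "df": 120
  },
  "virgin_female": {
    "sex": "female",
    "n_trials": 26,
    "antecedents": ["FW", "FQ", "FHMCA", "FMA", "FTDM", "FWDM", "FMM", "FWK", "FM", "FQHM"],
    "subsequents": ["FW", "FHMCA", "FMA", "FTDM", "FWDM", "FMM", "FWK", "FM", "FQHM", "FWP"],
    "row_totals": {"FW": 35, "FQ": 4, "FHMCA": 11, "FMA": 9, "FTDM": 17, "FWDM": 16, "FMM": 34, "FWK": 35, "FM": 26, "FQHM": 26},
    "col_totals": {"FW": 13, "FHMCA": 14, "FMA": 12, "FTDM": 16, "FWDM": 17, "FMM": 29, "FWK": 34, "FM": 26, "FQHM": 26, "FWP": 26},
    "grand_total": 213,
    "sum_chi_sq": 1116.24,
    "df": 81
  },
  "mated_female": {
    "sex": "female",
    "n_trials": 15,
    "antecedents": ["FW", "FTDM", "FWDM", "FMM", "FWK", "FM", "FQHM", "FWP"],
    "subsequents": ["FW", "FTDM", "FWDM", "FMM", "FWK", "FM", "FQHM", "FWP"],
    "row_totals": {"FW": 19, "FTDM": 10, "FWDM": 10, "FMM": 21, "FWK": 21, "FM": 18, "FQHM": 15, "FWP": 0},
    "col_totals": {"FW": 6, "FTDM": 10, "FWDM": 10, "FMM": 19, "FWK": 21, "FM": 15, "FQHM": 18, "FWP": 15},
    "grand_total": 114,
    "sum_chi_sq": 506.9,
    "df": 49
  }
}
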