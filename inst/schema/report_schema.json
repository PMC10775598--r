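{
  "title": "artdose cohort statistics report",
  "description": "Keys mirror the figure/table analogues of the analysis: fig1a (per-fraction EUD distributions), fig1c (homogeneity), fig2 (inter-vs-intra correlations), fig4 (dispersion and delta tests, percentile summaries), table2 (margin-vs-EUD), min_margins, summary (cohort arithmetic).",
  "required_keys": {
    "fig1a": ["p2_5_scheduled", "p2_5_adaptive", "dispersion", "location"],
    "fig1c": ["paired"],
    "fig2": [],
    "fig4": ["scale_tests", "delta_signed_rank", "inter_p95", "intra_p95"],
    "summary": ["n_patients", "n_fractions", "n_applied_adaptive", "pct_applied"]
  },
  "test_result_paths": [
    "fig1a/dispersion",
    "fig1a/location",
    "fig1c/paired"
  ]
}
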