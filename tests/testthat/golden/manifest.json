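{
  "package": "ccre",
  "version": "0.1.0",
  "seed": 101,
  "n_species": 12,
  "traits": ["leaf_area", "sla", "asat", "leaf_n"],
  "weighted_traits": ["leaf_area", "sla", "asat"],
  "method": "REML",
  "max_terms": 2,
  "alpha": 0.05,
  "decisions": {
    "scalings": {
      "mean_temp": "difference",
      "temp_var": "difference",
      "temp_range": "difference",
      "mean_precip": "log_ratio",
      "precip_var": "log_ratio",
      "precip_range": "log_ratio",
      "max_seasonal_precip": "log_ratio",
      "min_seasonal_precip": "log_ratio",
      "vpd": "log_ratio",
      "max_drought_dur": "log_ratio_p1",
      "max_heatwave_dur": "log_ratio_p1",
      "max_dryspell_dur": "log_ratio_p1"
    },
    "duration_offset": "+1 day inside duration log-ratios",
    "heatwave": {
      "window_len": 3,
      "pct": 0.95,
      "accl_days": 30,
      "min_run": 3
    },
    "drought": {
      "agg_days": 30,
      "pct": 0.1
    },
    "month_prior": "30-day trailing window before each anniversary",
    "imputation_rank": 1,
    "pca_scale_columns": false,
    "averaging": "zero-substitution",
    "aicc_likelihood": "ML"
  }
}
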