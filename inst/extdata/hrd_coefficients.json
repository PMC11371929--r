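{
  "description": "Logistic weighting over six homologous-recombination-deficiency features: exposure fractions of SBS3, SBS8, ID6 and RS3+RS5, the microhomology-deletion proportion among deletions, and the count of long (>=15 Mb) LOH segments. Each feature is standardized as (value - center) / scale before weighting. Editable; these defaults follow the published HRDetect-style convention, not any proprietary coefficient set.",
  "intercept": -3.0,
  "positive_cutoff": 0.7,
  "features": [
    {"name": "sbs3_fraction",     "center": 0.05, "scale": 0.10, "weight": 1.5},
    {"name": "sbs8_fraction",     "center": 0.05, "scale": 0.10, "weight": 0.8},
    {"name": "id6_fraction",      "center": 0.05, "scale": 0.10, "weight": 1.5},
    {"name": "rs_fraction",       "center": 0.10, "scale": 0.15, "weight": 1.5},
    {"name": "mh_del_proportion", "center": 0.10, "scale": 0.15, "weight": 1.5},
    {"name": "loh_segment_count", "center": 3.0,  "scale": 5.0,  "weight": 1.2}
  ]
}
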