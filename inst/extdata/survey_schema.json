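{
  "observations": {
    "site_id": "site_id",
    "park_id": "park_id",
    "year": "year",
    "survey_index": "survey_index",
    "season": "season",
    "survey_period": "survey_period",
    "sign_code": "sign_code",
    "count": "count",
    "notes": "notes"
  },
  "surveys": {
    "site_id": "site_id",
    "park_id": "park_id",
    "year": "year",
    "survey_index": "survey_index",
    "season": "season",
    "survey_period": "survey_period",
    "det_fs": "detected_fs",
    "det_fh": "detected_fh",
    "det_pc": "detected_pc",
    "det_ps": "detected_ps",
    "unamb_fs": "unambiguous_fs",
    "unamb_ps": "unambiguous_ps"
  },
  "sites": {
    "site_id": "site_id",
    "park_id": "park_id",
    "forb": "forb_pct",
    "rock": "rock_pct",
    "shrub": "shrub_pct",
    "complexity": "complexity"
  },
  "climate": {
    "site_id": "site_id",
    "year": "year",
    "tmaxmean": "tmaxmean_c",
    "precip": "precip_mm"
  }
}
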