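{
  "_comment": "UNVERIFIED placeholder descriptor for the externally deposited data set. The deposit's exact column layout has not been confirmed against a download; this mapping mirrors the native schema and must be edited to the real column names (and unit_scale, e.g. 0.1 for mm) before use. Field mapping is data, not code.",
  "columns": {
    "participant_id": "participant_id",
    "trial": "trial",
    "radius_cm": "radius_cm",
    "target_cm": "target_cm",
    "rel_error": "rel_error",
    "rewarded": "rewarded",
    "aspect_ratio": "aspect_ratio",
    "path_length_cm": "path_length_cm",
    "is_circular": "is_circular"
  },
  "unit_scale": 1
}
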