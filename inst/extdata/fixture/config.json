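{
  "maf_max": 0.04,
  "qual_min": 30,
  "votes_min": 4,
  "affected_min": 2,
  "prior": 0.041,
  "tier_bounds": {
    "low": 0.15,
    "medium": 0.4,
    "high": 0.7,
    "highest": 0.9
  },
  "manual_includes": ["FGB", "IL1A"],
  "network_eligible": ["CRP", "F2", "SERPINA1", "THBS1", "VWF", "PLAT"],
  "extra_includes": {
    "II2": [
      "FGB"
    ],
    "II3": [
      "FGB"
    ],
    "III2": [
      "FGB",
      "IL1A"
    ]
  }
}
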