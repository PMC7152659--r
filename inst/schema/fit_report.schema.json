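{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dhalokin fit report",
  "type": "object",
  "required": ["seed", "config_hash"],
  "properties": {
    "seed": { "type": "integer" },
    "config_hash": { "type": "string" },
    "global_fit": {
      "type": "object",
      "required": ["estimates", "standard_errors", "chi2_min", "n_points", "n_params", "converged"]
    },
    "mm_fit": {
      "type": "object",
      "required": ["kcat", "Km", "kcat_over_Km"]
    },
    "contours": { "type": "object" },
    "rate_limiting_step": {},
    "Ks": { "type": "object" }
  }
}
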