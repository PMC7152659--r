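{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dhalokin MSM report",
  "type": "object",
  "required": ["seed", "config_hash", "n_states", "lag", "equilibrium_distribution"],
  "properties": {
    "seed": { "type": "integer" },
    "config_hash": { "type": "string" },
    "n_states": { "type": "integer" },
    "lag": { "type": "integer" },
    "equilibrium_distribution": { "type": "array", "items": { "type": "number" } },
    "implied_timescales": {},
    "ck_max_discrepancy": {},
    "pathway_fractions": { "type": "object" },
    "nac_fraction": { "type": "number" }
  }
}
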