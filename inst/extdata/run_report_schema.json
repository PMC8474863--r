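{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rhdamp run report",
  "type": "object",
  "required": ["diagnostic_counts", "ratios", "error_ratios", "qc_flags"],
  "properties": {
    "diagnostic_counts": {
      "type": "object",
      "required": ["upstream_box", "downstream_box", "RHD_wt", "RHD_var", "RHCE"],
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "ratios": {
      "type": "object",
      "required": ["box", "exon9"],
      "properties": {
        "box": {"$ref": "#/$defs/ratio_group"},
        "exon9": {"$ref": "#/$defs/ratio_group"}
      }
    },
    "error_ratios": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["max", "median", "pooled", "n_analyzable"]
      }
    },
    "preprocess_ledger": {"type": ["object", "null"]},
    "dedup": {"type": ["object", "null"]},
    "qc_flags": {"type": "array"}
  },
  "$defs": {
    "ratio_group": {
      "type": "object",
      "required": ["pct", "counts"]
    }
  }
}
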