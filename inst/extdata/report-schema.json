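{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ramresp pipeline report",
  "type": "object",
  "required": ["version", "config_hash", "seed", "metabolic_summary",
               "crit_oxygen", "n_records", "n_qc_pass"],
  "properties": {
    "version": {"type": "string"},
    "config_hash": {"type": "string"},
    "seed": {"type": ["integer", "null"]},
    "n_records": {"type": "integer"},
    "n_qc_pass": {"type": "integer"},
    "metabolic_summary": {
      "type": "object",
      "required": ["mmr", "mrmr", "aerobic_scope"],
      "properties": {
        "mmr": {"type": "number"},
        "mrmr": {"type": "number"},
        "aerobic_scope": {"type": "number"},
        "n_records_used": {"type": "integer"},
        "k_top": {"type": "integer"},
        "k_bottom": {"type": "integer"}
      }
    },
    "crit_oxygen": {
      "type": "object",
      "required": ["found"],
      "properties": {
        "found": {"type": "boolean"},
        "ccrit": {"type": ["number", "null"]},
        "scrit_pct": {"type": ["number", "null"]},
        "pcrit": {"type": ["number", "null"]},
        "n_points": {"type": "integer"}
      }
    },
    "activity_present": {"type": "boolean"}
  }
}
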