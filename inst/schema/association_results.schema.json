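{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pleioscan association results",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["protein", "study_label", "beta", "se", "ci_low", "ci_high",
                 "p_value", "q_value", "ev_point", "ev_ci", "notable",
                 "transform", "n_used"],
    "properties": {
      "protein": {"type": "string"},
      "study_label": {"type": "string"},
      "beta": {"type": "number"},
      "se": {"type": "number"},
      "ci_low": {"type": "number"},
      "ci_high": {"type": "number"},
      "p_value": {"type": "number", "minimum": 0, "maximum": 1},
      "q_value": {"type": "number", "minimum": 0, "maximum": 1},
      "ev_point": {"type": "number", "minimum": 1},
      "ev_ci": {"type": "number", "minimum": 1},
      "notable": {"type": "boolean"},
      "transform": {"type": "string", "enum": ["identity", "log"]},
      "n_used": {"type": "integer", "minimum": 1},
      "n_outliers_removed": {"type": "integer", "minimum": 0},
      "n_influential_removed": {"type": "integer", "minimum": 0},
      "knots": {"type": "string"}
    }
  }
}
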