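{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pecklat analysis report",
  "type": "object",
  "required": [
    "exclusions",
    "population",
    "strength",
    "accuracy",
    "balanced_errors",
    "efficiency",
    "grouping_checks",
    "flock_mc",
    "config"
  ],
  "$defs": {
    "test": {
      "oneOf": [
        {
          "type": "object",
          "required": ["method", "statistic", "p_value", "n", "exact"],
          "properties": {
            "method": {
              "enum": [
                "binomial_z",
                "binomial_exact",
                "wilcoxon_signed_rank",
                "mann_whitney",
                "kruskal_wallis",
                "kappa"
              ]
            },
            "statistic": { "type": "number" },
            "p_value": { "type": "number", "minimum": 0, "maximum": 1 },
            "n": { "type": "integer" },
            "exact": { "type": "boolean" }
          }
        },
        {
          "type": "object",
          "required": ["omitted"],
          "properties": { "omitted": { "const": true }, "reason": { "type": "string" } }
        }
      ]
    }
  },
  "properties": {
    "exclusions": {
      "type": "object",
      "required": ["n_input", "n_interrupted", "n_below_min_inspections", "n_analyzed"]
    },
    "strength": { "$ref": "#/$defs/test" },
    "accuracy": {
      "type": "object",
      "additionalProperties": { "$ref": "#/$defs/test" }
    },
    "efficiency": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": { "$ref": "#/$defs/test" }
      }
    },
    "grouping_checks": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": { "$ref": "#/$defs/test" }
      }
    },
    "config": { "type": "object" }
  }
}
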