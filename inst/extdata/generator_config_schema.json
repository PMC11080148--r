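{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fedqi generator configuration",
  "type": "object",
  "required": ["center_id", "n_patients", "seed"],
  "additionalProperties": false,
  "properties": {
    "center_id": {"type": "string"},
    "n_patients": {"type": "integer", "minimum": 0},
    "seed": {"type": "integer"},
    "rectum_fraction": {"$ref": "#/$defs/probability"},
    "referred_fraction": {"$ref": "#/$defs/probability"},
    "neoadjuvant_fraction": {"$ref": "#/$defs/probability"},
    "complication_prob": {"$ref": "#/$defs/probability"},
    "short_wait_fraction": {"$ref": "#/$defs/probability"},
    "quota_counts": {
      "type": "object",
      "description": "Exact-marginal mode: per localization [denominator, numerator]; the numerator is the short-waiting-time count for colon and the postoperative-complication count for rectum. Denominators must sum to at most n_patients; remaining records are generated as referred.",
      "additionalProperties": false,
      "properties": {
        "colon": {"$ref": "#/$defs/quota"},
        "rectum": {"$ref": "#/$defs/quota"}
      }
    },
    "waiting_time_days": {"$ref": "#/$defs/distribution"},
    "age": {"$ref": "#/$defs/distribution"},
    "bmi": {"$ref": "#/$defs/distribution"},
    "charlson": {"$ref": "#/$defs/distribution"},
    "asa": {"$ref": "#/$defs/distribution"},
    "preop_complication": {"$ref": "#/$defs/distribution"}
  },
  "$defs": {
    "probability": {"type": "number", "minimum": 0, "maximum": 1},
    "quota": {
      "type": "array",
      "items": {"type": "integer", "minimum": 0},
      "minItems": 2,
      "maxItems": 2
    },
    "distribution": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": {"enum": ["normal", "lognormal", "poisson", "categorical", "uniform_int", "bernoulli", "constant"]}
      }
    }
  }
}
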