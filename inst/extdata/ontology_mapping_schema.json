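{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fedqi column-to-ontology mapping",
  "type": "object",
  "required": ["entries"],
  "properties": {
    "note": {"type": "string"},
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["column_name", "predicate_iri", "datatype"],
        "additionalProperties": false,
        "properties": {
          "column_name": {"type": "string"},
          "predicate_iri": {"type": "string", "format": "iri"},
          "datatype": {"enum": ["date", "boolean", "integer", "decimal", "coded_text"]},
          "concept_code": {"type": "string", "description": "terminology (e.g. SNOMED CT) concept identifier annotating the variable"},
          "value_codes": {
            "type": "object",
            "additionalProperties": {"type": "string"},
            "description": "for enumerated columns: cell value to concept code; must cover the column's domain"
          }
        }
      }
    }
  }
}
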