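{
  "note": "Default column-to-ontology mapping for the colorectal-surgery flat table. The SNOMED CT concept codes below are plausible placeholders anchoring each variable's meaning; they are configuration, not asserted terminology bindings - edit them to match a local terminology service.",
  "entries": [
    {"column_name": "patient_id", "predicate_iri": "https://w3id.org/fedqi/ontology#patientId", "datatype": "coded_text", "concept_code": "422549004"},
    {"column_name": "hospital_id", "predicate_iri": "https://w3id.org/fedqi/ontology#hospitalId", "datatype": "coded_text", "concept_code": "22232009"},
    {"column_name": "tumor_localization", "predicate_iri": "https://w3id.org/fedqi/ontology#tumorLocalization", "datatype": "coded_text", "concept_code": "399687005",
     "value_codes": {"colon": "363406005", "rectum": "363351006"}},
    {"column_name": "referred", "predicate_iri": "https://w3id.org/fedqi/ontology#referred", "datatype": "boolean", "concept_code": "3457005",
     "value_codes": {"yes": "3457005", "no": "441889009"}},
    {"column_name": "date_of_diagnosis", "predicate_iri": "https://w3id.org/fedqi/ontology#dateOfDiagnosis", "datatype": "date", "concept_code": "432213005"},
    {"column_name": "date_neoadjuvant_start", "predicate_iri": "https://w3id.org/fedqi/ontology#dateNeoadjuvantStart", "datatype": "date", "concept_code": "703423002"},
    {"column_name": "date_of_surgery", "predicate_iri": "https://w3id.org/fedqi/ontology#dateOfSurgery", "datatype": "date", "concept_code": "387713003"},
    {"column_name": "resection_type", "predicate_iri": "https://w3id.org/fedqi/ontology#resectionType", "datatype": "coded_text", "concept_code": "87795007"},
    {"column_name": "age", "predicate_iri": "https://w3id.org/fedqi/ontology#age", "datatype": "integer", "concept_code": "424144002"},
    {"column_name": "bmi", "predicate_iri": "https://w3id.org/fedqi/ontology#bmi", "datatype": "decimal", "concept_code": "60621009"},
    {"column_name": "charlson_score", "predicate_iri": "https://w3id.org/fedqi/ontology#charlsonScore", "datatype": "integer", "concept_code": "762713009"},
    {"column_name": "asa_class", "predicate_iri": "https://w3id.org/fedqi/ontology#asaClass", "datatype": "integer", "concept_code": "302132005"},
    {"column_name": "preop_tumor_complication", "predicate_iri": "https://w3id.org/fedqi/ontology#preopTumorComplication", "datatype": "boolean", "concept_code": "116223007"},
    {"column_name": "postop_complication", "predicate_iri": "https://w3id.org/fedqi/ontology#postopComplication", "datatype": "boolean", "concept_code": "385486001"}
  ]
}
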