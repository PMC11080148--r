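# Cohort retrieval for quality indicator 2b (waiting time between
# diagnosis and start of therapy). Variable names match the flat-table
# columns so the local algorithm receives canonically named rows.
PREFIX fq: <https://w3id.org/fedqi/ontology#>
SELECT ?patient ?tumor_localization ?referred ?date_of_diagnosis
       ?date_neoadjuvant_start ?date_of_surgery
WHERE {
  ?patient a fq:Patient ;
           fq:tumorLocalization ?tumor_localization ;
           fq:referred ?referred ;
           fq:dateOfDiagnosis ?date_of_diagnosis ;
           fq:dateOfSurgery ?date_of_surgery .
  OPTIONAL { ?patient fq:dateNeoadjuvantStart ?date_neoadjuvant_start . }
}
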