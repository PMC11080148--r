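# Cohort retrieval for quality indicator 8 (postoperative complication
# rate). The case-mix variables (age, BMI, Charlson, ASA, preoperative
# complications) are retrieved and carried through but not used for
# adjustment: the reported rate is crude.
PREFIX fq: <https://w3id.org/fedqi/ontology#>
SELECT ?patient ?tumor_localization ?referred ?date_of_surgery ?age ?bmi
       ?charlson_score ?asa_class ?preop_tumor_complication
       ?postop_complication
WHERE {
  ?patient a fq:Patient ;
           fq:tumorLocalization ?tumor_localization ;
           fq:referred ?referred ;
           fq:dateOfSurgery ?date_of_surgery ;
           fq:age ?age ;
           fq:bmi ?bmi ;
           fq:charlsonScore ?charlson_score ;
           fq:asaClass ?asa_class ;
           fq:preopTumorComplication ?preop_tumor_complication ;
           fq:postopComplication ?postop_complication .
}
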