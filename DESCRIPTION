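Package: fedqi
Title: Federated Calculation of Colorectal Surgery Quality Indicators over FAIR Data Stations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-center colorectal-surgery patient tables into FAIR
    RDF graphs annotated with clinical terminology codes, hosts each graph
    behind a query-only data station, dispatches federated "trains" that
    compute the Dutch ColoRectal Audit quality indicators 2b (short waiting
    time between diagnosis and start of therapy) and 8 (postoperative
    complication rate) locally, aggregates only counts centrally, and renders
    the two cross-center comparison plots. Includes a configurable synthetic
    electronic-health-record generator (Bernoulli and exact-quota sampling
    modes) so the whole pipeline is testable without hospital data, an
    embedded SPARQL SELECT engine, and Turtle/N-Triples serialization.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
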