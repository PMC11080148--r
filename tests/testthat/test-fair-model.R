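# FAIRification: triple counts by direct enumeration, missing-value
# handling, round trips through the flat view and through both RDF
# serializations, with python/rdflib as an independent parser oracle.

test_that("a complete record yields one type triple plus one per mapped cell", {
  tab <- tiny_table()
  g <- triplify(tab)
  # per record: 1 type + 14 mapped columns, minus absent neoadjuvant cells
  n_missing <- sum(is.na(tab$records$date_neoadjuvant_start))
  expect_equal(patient_triple_count(g), 3L * 15L - n_missing)

  # record p2 has all 14 cells present
  subj <- "https://w3id.org/fedqi/patient/demo/p2"
  expect_equal(sum(g$triples$subject == subj), 15L)

  # no triple for the absent neoadjuvant date of p1
  pred <- "https://w3id.org/fedqi/ontology#dateNeoadjuvantStart"
  with_neo <- g$triples$subject[g$triples$predicate == pred]
  expect_false("https://w3id.org/fedqi/patient/demo/p1" %in% with_neo)
  expect_true(subj %in% with_neo)

  # every literal carries the datatype the mapping declares
  lit <- g$triples[!is.na(g$triples$datatype) &
                     g$triples$predicate == "https://w3id.org/fedqi/ontology#dateOfSurgery", ]
  expect_true(all(lit$datatype == "http://www.w3.org/2001/XMLSchema#date"))

  empty <- triplify(flat_table("e", fedqi:::empty_records()))
  expect_equal(patient_triple_count(empty), 0L)
})

test_that("terminology annotations come from the mapping, at vocabulary level", {
  g <- triplify(tiny_table())
  sn <- g$triples[g$triples$predicate == "https://w3id.org/fedqi/ontology#snomedCode", ]
  expect_gt(nrow(sn), 0L)
  expect_true(all(startsWith(sn$object, "http://snomed.info/id/")))
  # predicate-level annotation for tumor localization present
  expect_true("https://w3id.org/fedqi/ontology#tumorLocalization" %in% sn$subject)
})

test_that("triplify rejects unmapped columns and uncovered coded values", {
  tab <- tiny_table()
  tab$records$extra_notes <- "free text"
  expect_error(triplify(tab), "extra_notes")

  # value outside value_codes names row, column and value
  tab2 <- tiny_table()
  tab2$records$tumor_localization[2] <- "sigmoid"
  err <- tryCatch(triplify(tab2), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "tumor_localization")
  expect_match(conditionMessage(err), "sigmoid")
})

test_that("flat view inverts triplification up to record order", {
  tab <- generate_center(generator_config("c", 40L, seed = 8L))
  g <- triplify(tab)
  back <- flat_view(g)
  ord <- order(tab$records$patient_id)
  expect_equal(back$records, tab$records[ord, ], ignore_attr = TRUE)
  expect_identical(back$center_id, tab$center_id)

  # an extra unrelated triple is ignored
  g2 <- fair_graph(rbind(g$triples,
                         data.frame(subject = "https://example.org/x",
                                    predicate = "https://example.org/p",
                                    object = "y",
                                    datatype = "http://www.w3.org/2001/XMLSchema#string")),
                   base_namespace = g$base_namespace)
  expect_equal(flat_view(g2)$records, back$records, ignore_attr = TRUE)

  expect_equal(nrow(flat_view(fair_graph())$records), 0L)
})

test_that("round trips through Turtle and N-Triples are graph-isomorphic", {
  g <- triplify(tiny_table())
  ttl <- tempfile(fileext = ".ttl"); nt <- tempfile(fileext = ".nt")
  serialize_graph(g, ttl, "turtle")
  serialize_graph(g, nt, "ntriples")
  expect_true(graphs_isomorphic(g, parse_graph(ttl)))
  expect_true(graphs_isomorphic(g, parse_graph(nt)))
  expect_true(graphs_isomorphic(parse_graph(ttl), parse_graph(nt)))

  ge <- fair_graph()
  serialize_graph(ge, ttl, "turtle")
  expect_true(graphs_isomorphic(ge, parse_graph(ttl)))

  expect_error(serialize_graph(g, ttl, "trig"), "'arg'")
})

test_that("a standards-conformant external parser reads the Turtle output", {
  g <- triplify(generate_center(generator_config("ox", 15L, seed = 4L)))
  ttl <- tempfile(fileext = ".ttl")
  serialize_graph(g, ttl, "turtle")
  res <- rdflib_oracle(ttl, system.file("queries", "qi8.rq", package = "fedqi"))
  expect_equal(nrow(res), 15L)
  # spot-check one typed value against the engine's own result
  mine <- sparql_select(g, shipped_query("qi8"))
  expect_setequal(res$patient, mine$patient)
  expect_equal(sort(as.integer(res$age)), sort(mine$age))
})
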