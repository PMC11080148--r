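# FAIRification: a column-to-ontology mapping drives conversion of a flat
# table into an RDF graph (one patient subject per record, one predicate per
# variable, typed literals, terminology annotations at the vocabulary level)
# and the inverse flat view used for round-trip checking.

SCT_NS <- "http://snomed.info/id/"

ontology_ns <- function(base) paste0(base, "/ontology#")

#' Load a column-to-ontology mapping
#'
#' The mapping JSON has an `entries` array; each entry gives `column_name`,
#' an absolute `predicate_iri`, a `datatype` (`date`, `boolean`, `integer`,
#' `decimal` or `coded_text`), an optional `concept_code` (a SNOMED CT
#' identifier anchoring the variable's meaning) and, for enumerated columns,
#' `value_codes` mapping each cell value to a concept code. A JSON-schema
#' document ships as `inst/extdata/ontology_mapping_schema.json`, and a
#' default mapping for the full variable set as
#' `inst/extdata/mapping_default.json` — its concept codes are plausible
#' placeholders and explicitly configurable, not asserted terminology
#' bindings.
#'
#' @param path mapping JSON file; `NULL` loads the shipped default.
#' @return object of class `ontology_mapping` (list of entries keyed by
#'   column name).
#' @export
read_ontology_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mapping_default.json", package = "fedqi",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$entries)) stop("mapping file has no 'entries' array: ", path,
                                 call. = FALSE)
  entries <- list()
  for (e in raw$entries) {
    for (f in c("column_name", "predicate_iri", "datatype")) {
      if (is.null(e[[f]])) {
        stop("mapping entry missing required field '", f, "'", call. = FALSE)
      }
    }
    if (!grepl("^[a-z][a-z0-9+.-]*://", e$predicate_iri)) {
      stop("mapping entry '", e$column_name, "': predicate_iri must be absolute: ",
           e$predicate_iri, call. = FALSE)
    }
    if (!e$datatype %in% c("date", "boolean", "integer", "decimal", "coded_text")) {
      stop("mapping entry '", e$column_name, "': unknown datatype '", e$datatype, "'",
           call. = FALSE)
    }
    if (!is.null(entries[[e$column_name]])) {
      stop("duplicate mapping entry for column '", e$column_name, "'", call. = FALSE)
    }
    entries[[e$column_name]] <- e
  }
  structure(entries, class = "ontology_mapping")
}

mapping_datatype_iri <- function(datatype) {
  switch(datatype,
         date = xsd_iri("date"),
         boolean = xsd_iri("boolean"),
         integer = xsd_iri("integer"),
         decimal = xsd_iri("decimal"),
         coded_text = xsd_iri("string"),
         stop("unknown mapping datatype: ", datatype, call. = FALSE))
}

column_to_lexical <- function(values, datatype, col, value_codes = NULL) {
  out <- rep(NA_character_, length(values))
  present <- !is.na(values)
  out[present] <- switch(
    datatype,
    date = format(values[present], "%Y-%m-%d"),
    boolean = ifelse(values[present], "true", "false"),
    integer = as.character(as.integer(values[present])),
    decimal = as.character(values[present]),
    coded_text = as.character(values[present])
  )
  if (datatype == "coded_text" && !is.null(value_codes)) {
    bad <- which(present & !(out %in% names(value_codes)))
    if (length(bad) > 0L) {
      stop(sprintf("row %d, column '%s': value '%s' not covered by the mapping's value_codes",
                   bad[1L], col, out[bad[1L]]), call. = FALSE)
    }
  }
  out
}

lexical_to_column <- function(lex, datatype) {
  switch(datatype,
         date = as.Date(lex, format = "%Y-%m-%d"),
         boolean = lex == "true",
         integer = as.integer(lex),
         decimal = as.numeric(lex),
         coded_text = lex)
}

patient_iri <- function(base, center_id, patient_id) {
  paste0(base, "/patient/", center_id, "/", patient_id)
}

dataset_iri <- function(base, center_id) paste0(base, "/dataset/", center_id)

#' Convert a flat table into a FAIR RDF graph
#'
#' The schema is a star per patient: a subject IRI minted as
#' `{base}/patient/{center}/{patient_id}` carries one `rdf:type fq:Patient`
#' triple plus one typed-literal triple per mapped, non-missing cell.
#' Missing optional cells produce no triple (no nulls, no blank nodes).
#' Terminology anchoring is vocabulary-level: each mapped predicate links to
#' its concept code via an annotation triple (`fq:snomedCode`), and
#' enumerated values get per-value annotation subjects; the codes come from
#' the mapping file, never from code. One dataset-level provenance triple
#' records the center id.
#'
#' @param table a [flat_table()].
#' @param mapping an [read_ontology_mapping()] result covering every table
#'   column (an unmapped column is an error naming it).
#' @param base_namespace IRI base for minted subjects.
#' @return a [fair_graph()].
#' @export
triplify <- function(table, mapping = read_ontology_mapping(),
                     base_namespace = DEFAULT_BASE_NS) {
  stopifnot(inherits(table, "flat_table"), inherits(mapping, "ontology_mapping"))
  r <- table$records
  unmapped <- setdiff(names(r), names(mapping))
  if (length(unmapped) > 0L) {
    stop("unmapped column '", unmapped[1L], "': add it to the ontology mapping",
         call. = FALSE)
  }
  ont <- ontology_ns(base_namespace)
  subj <- if (nrow(r) > 0L) {
    patient_iri(base_namespace, table$center_id, r$patient_id)
  } else {
    character(0)
  }
  parts <- list()
  if (nrow(r) > 0L) {
    parts[[1L]] <- data.frame(subject = subj, predicate = RDF_TYPE,
                              object = paste0(ont, "Patient"),
                              datatype = NA_character_, stringsAsFactors = FALSE)
  }
  vocab <- list(data.frame(subject = dataset_iri(base_namespace, table$center_id),
                           predicate = paste0(ont, "centerId"),
                           object = table$center_id,
                           datatype = xsd_iri("string"), stringsAsFactors = FALSE))
  for (col in names(r)) {
    e <- mapping[[col]]
    codes <- if (is.null(e$value_codes)) NULL else e$value_codes
    lex <- column_to_lexical(r[[col]], e$datatype, col, codes)
    keep <- !is.na(lex)
    if (any(keep)) {
      parts[[length(parts) + 1L]] <- data.frame(
        subject = subj[keep], predicate = e$predicate_iri, object = lex[keep],
        datatype = mapping_datatype_iri(e$datatype), stringsAsFactors = FALSE)
    }
    if (!is.null(e$concept_code)) {
      vocab[[length(vocab) + 1L]] <- data.frame(
        subject = e$predicate_iri, predicate = paste0(ont, "snomedCode"),
        object = paste0(SCT_NS, e$concept_code), datatype = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (!is.null(codes)) {
      for (val in names(codes)) {
        vsubj <- paste0(e$predicate_iri, "/value/", val)
        vocab[[length(vocab) + 1L]] <- data.frame(
          subject = c(vsubj, vsubj),
          predicate = c(paste0(ont, "forValue"), paste0(ont, "snomedCode")),
          object = c(val, paste0(SCT_NS, codes[[val]])),
          datatype = c(xsd_iri("string"), NA_character_), stringsAsFactors = FALSE)
      }
    }
  }
  fair_graph(do.call(rbind, c(parts, vocab)), base_namespace = base_namespace)
}

#' Count patient-subject triples in a graph
#'
#' Triples whose subject is a minted patient IRI: per record this is exactly
#' 1 (the type declaration) + the number of mapped non-missing cells.
#' Vocabulary annotation and provenance triples are excluded.
#'
#' @param graph a [fair_graph()].
#' @return integer count.
#' @export
patient_triple_count <- function(graph) {
  sum(startsWith(graph$triples$subject, paste0(graph$base_namespace, "/patient/")))
}

#' Rebuild the flat table view of a FAIRified graph
#'
#' Inverse of [triplify()] for graphs it produced: collects each patient
#' subject's mapped predicates back into one row; unmapped triples
#' (vocabulary annotations, provenance, extraneous statements) are ignored.
#' Record order follows patient id, so `flat_view(triplify(t))` equals `t`
#' up to row order.
#'
#' @param graph a [fair_graph()] produced by [triplify()] with `mapping`.
#' @param mapping the same [read_ontology_mapping()].
#' @param center_id center label; default recovers it from the dataset
#'   provenance triple.
#' @return a [flat_table()].
#' @export
flat_view <- function(graph, mapping = read_ontology_mapping(), center_id = NULL) {
  t <- graph$triples
  ont <- ontology_ns(graph$base_namespace)
  if (is.null(center_id)) {
    prov <- t$predicate == paste0(ont, "centerId") &
      startsWith(t$subject, paste0(graph$base_namespace, "/dataset/"))
    if (any(prov)) center_id <- t$object[which(prov)[1L]] else center_id <- "unknown"
  }
  subj <- sort(unique(t$subject[t$predicate == RDF_TYPE &
                                  t$object == paste0(ont, "Patient")]))
  if (length(subj) == 0L) return(flat_table(center_id, empty_records()))

  cols <- flat_table_columns()
  out <- empty_records()[rep(1L, 0L), ]
  value_of <- function(pred_iri) {
    hit <- t[t$predicate == pred_iri & t$subject %in% subj, c("subject", "object")]
    hit$object[match(subj, hit$subject)]
  }
  lst <- list()
  for (col in cols) {
    e <- mapping[[col]]
    if (is.null(e)) stop("mapping does not cover column '", col, "'", call. = FALSE)
    lst[[col]] <- lexical_to_column(value_of(e$predicate_iri), e$datatype)
  }
  records <- as.data.frame(lst, stringsAsFactors = FALSE)
  required <- setdiff(cols, optional_columns())
  for (col in required) {
    bad <- is.na(records[[col]])
    if (any(bad)) {
      stop("graph subjects missing required predicate '", col, "': ",
           paste(utils::head(subj[bad], 3L), collapse = ", "), call. = FALSE)
    }
  }
  records <- records[order(records$patient_id), , drop = FALSE]
  rownames(records) <- NULL
  flat_table(center_id, records)
}
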