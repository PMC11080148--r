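# A FAIR data station hosts one center's graph behind a query-only boundary:
# callers hand it a train (query + indicator spec) and get back an
# aggregate-only payload. The graph itself is captured in a private closure
# environment, so the station object exposes no graph accessor.

#' Station access policy
#'
#' @param min_cell_size small-cell suppression threshold: when positive, a
#'   result whose numerator or denominator is positive but below the
#'   threshold is returned with counts and ratio replaced by an explicit
#'   suppressed marker. Default 0 (suppression off), so small-center counts
#'   remain reproducible.
#' @return a `station_policy` list.
#' @export
station_policy <- function(min_cell_size = 0L) {
  stopifnot(is.numeric(min_cell_size), min_cell_size >= 0)
  structure(list(allowed_result_kinds = "aggregate-only",
                 min_cell_size = as.integer(min_cell_size)),
            class = "station_policy")
}

apply_suppression <- function(result, policy) {
  m <- policy$min_cell_size
  if (m > 0L && !result$suppressed &&
      ((result$denominator > 0L && result$denominator < m) ||
       (result$numerator > 0L && result$numerator < m))) {
    result <- local_result(result$center_id, result$indicator_id,
                           NA_integer_, NA_integer_, suppressed = TRUE)
  }
  result
}

#' Host a FAIR graph as a data station
#'
#' The returned station exposes exactly two capabilities to an orchestrator:
#' `accept_train(train)`, which executes the train's retrieval query and
#' local indicator algorithm inside the station and stores the aggregate
#' payload, and `return_payload()`, which hands that payload back. The
#' hosted graph is immutable through this interface and never part of any
#' payload.
#'
#' @param graph a [fair_graph()] (typically from [triplify()]).
#' @param center_id center label for results.
#' @param policy a [station_policy()].
#' @return object of class `fair_station`.
#' @export
host_station <- function(graph, center_id, policy = station_policy()) {
  stopifnot(inherits(graph, "fair_graph"), inherits(policy, "station_policy"))
  force(graph); force(center_id); force(policy)
  payload_box <- new.env(parent = emptyenv())
  payload_box$payload <- NULL
  accept_train <- function(train) {
    stopifnot(inherits(train, "qi_train"))
    rows <- sparql_select(graph, train$sparql_query)
    result <- compute_indicator(rows, train$indicator_spec, center_id)
    result <- apply_suppression(result, policy)
    payload_box$payload <- unclass(result)
    invisible(TRUE)
  }
  return_payload <- function() payload_box$payload
  structure(list(center_id = center_id, policy = policy,
                 accept_train = accept_train, return_payload = return_payload),
            class = "fair_station")
}

#' @export
print.fair_station <- function(x, ...) {
  cat(sprintf("<fair_station> center '%s' (aggregate-only, min cell size %d)\n",
              x$center_id, x$policy$min_cell_size))
  invisible(x)
}

#' Execute a SPARQL query inside a station
#'
#' Station-internal retrieval step: this is what a train's local algorithm
#' calls while running inside the station boundary. It returns record-level
#' rows and must therefore never be used to build a payload that leaves the
#' station — payloads are validated against the aggregate-only schema by
#' [validate_payload()] in [run_federated()].
#'
#' @param station a [host_station()] result.
#' @param query SPARQL SELECT text.
#' @return typed data.frame of bindings (see [sparql_select()]).
#' @export
execute_sparql <- function(station, query) {
  stopifnot(inherits(station, "fair_station"))
  # reach into the hosting closure: the graph is not a list element
  graph <- environment(station$accept_train)$graph
  sparql_select(graph, query)
}

#' Load a station from a serialized graph file
#'
#' Convenience for the command-line pipeline: parse a Turtle/N-Triples file
#' and host it.
#'
#' @param path RDF file written by [serialize_graph()].
#' @param center_id center label; default recovered from the graph's
#'   dataset provenance triple.
#' @param policy a [station_policy()].
#' @return a `fair_station`.
#' @export
load_station <- function(path, center_id = NULL, policy = station_policy()) {
  graph <- parse_graph(path)
  if (is.null(center_id)) {
    t <- graph$triples
    prov <- t$predicate == paste0(ontology_ns(graph$base_namespace), "centerId")
    center_id <- if (any(prov)) t$object[which(prov)[1L]] else
      tools::file_path_sans_ext(basename(path))
  }
  host_station(graph, center_id, policy)
}
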