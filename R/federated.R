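# The train abstraction and the local/master split: a train (retrieval
# query + indicator spec, no data) visits every station; each station runs
# the local algorithm and emits an aggregate payload; the master combines
# the payloads into the cross-center comparison statistics.

#' Build a train
#'
#' A train carries only the data-retrieval query and the indicator
#' parameters — never data. The shipped queries live under
#' `system.file("queries", package = "fedqi")`, one file per indicator.
#'
#' @param indicator_spec an [indicator_spec()].
#' @param sparql_query SPARQL SELECT text; default loads the shipped query
#'   for the spec's indicator.
#' @param train_id label for logs and result files.
#' @return object of class `qi_train`.
#' @export
build_train <- function(indicator_spec, sparql_query = NULL,
                        train_id = indicator_spec$indicator_id) {
  stopifnot(inherits(indicator_spec, "indicator_spec"))
  if (is.null(sparql_query)) {
    qfile <- system.file("queries", paste0(indicator_spec$indicator_id, ".rq"),
                         package = "fedqi", mustWork = TRUE)
    sparql_query <- paste(readLines(qfile, warn = FALSE), collapse = "\n")
  }
  structure(list(train_id = train_id, sparql_query = sparql_query,
                 indicator_spec = indicator_spec),
            class = "qi_train")
}

#' Read a train definition from JSON
#'
#' Format: `{"train_id": ..., "query_file": ..., "indicator_spec":
#' {"indicator_id": ..., "localization": ..., "waiting_threshold_days": ...,
#' "exclude_referred": ...}}`. `query_file` is resolved relative to the
#' definition file; when omitted the shipped query for the indicator is
#' used.
#'
#' @param path JSON train definition.
#' @return a `qi_train`.
#' @export
read_train <- function(path) {
  if (!file.exists(path)) stop("train file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$indicator_spec$indicator_id)) {
    stop("train definition missing indicator_spec.indicator_id: ", path, call. = FALSE)
  }
  spec <- do.call(indicator_spec, raw$indicator_spec)
  query <- NULL
  if (!is.null(raw$query_file)) {
    qpath <- if (file.exists(raw$query_file)) raw$query_file else
      file.path(dirname(path), raw$query_file)
    if (!file.exists(qpath)) stop("train query file not found: ", qpath, call. = FALSE)
    query <- paste(readLines(qpath, warn = FALSE), collapse = "\n")
  }
  build_train(spec, query, train_id = raw$train_id %||% spec$indicator_id)
}

#' Validate a candidate train payload against the aggregate-only schema
#'
#' Closed-world check of the local-result contract: the payload must carry
#' exactly the fields `center_id`, `indicator_id`, `denominator`,
#' `numerator`, `ratio`, `suppressed` with the right types and the count
#' invariants (`0 <= numerator <= denominator`, `ratio = numerator /
#' denominator` when defined). Unknown fields are violations — this is what
#' stops a train smuggling record-level data past the station boundary.
#'
#' @param payload a candidate payload (named list).
#' @return character vector of violations; empty means pass.
#' @export
validate_payload <- function(payload) {
  violations <- character(0)
  expected <- c("center_id", "indicator_id", "denominator", "numerator",
                "ratio", "suppressed")
  if (!is.list(payload)) return("payload is not a named list")
  extra <- setdiff(names(payload), expected)
  if (length(extra) > 0L) {
    violations <- c(violations,
                    paste0("unexpected field '", extra, "' (record-level or unknown data)"))
  }
  miss <- setdiff(expected, names(payload))
  if (length(miss) > 0L) {
    violations <- c(violations, paste0("missing field '", miss, "'"))
    return(violations)
  }
  scalar <- vapply(payload[expected], function(x) length(x) == 1L, logical(1L))
  if (!all(scalar)) {
    violations <- c(violations,
                    paste0("field '", expected[!scalar], "' is not a scalar"))
    return(violations)
  }
  num <- payload$numerator; den <- payload$denominator
  if (isTRUE(payload$suppressed)) {
    if (!is.na(num) || !is.na(den) || !is.na(payload$ratio)) {
      violations <- c(violations, "suppressed payload must carry NA counts and ratio")
    }
    return(violations)
  }
  if (!is.numeric(num) || !is.numeric(den) || is.na(num) || is.na(den)) {
    return(c(violations, "numerator and denominator must be numbers"))
  }
  if (num < 0 || den < 0) violations <- c(violations, "negative count")
  if (num > den) violations <- c(violations, "numerator exceeds denominator")
  if (den > 0) {
    if (is.na(payload$ratio) || abs(payload$ratio - num / den) > 1e-12) {
      violations <- c(violations, "ratio does not equal numerator / denominator")
    }
  } else if (!is.na(payload$ratio)) {
    violations <- c(violations, "ratio must be undefined when denominator is zero")
  }
  violations
}

#' Run one train at one station
#'
#' Dispatches the train through the station's `accept_train` capability and
#' retrieves the payload through `return_payload` — the only two station
#' operations an orchestrator uses. The payload is validated against the
#' aggregate-only schema before being returned.
#'
#' @param station a [host_station()] result.
#' @param train a [build_train()] result.
#' @return a `local_result`.
#' @export
run_train <- function(station, train) {
  stopifnot(inherits(station, "fair_station"))
  station$accept_train(train)
  payload <- station$return_payload()
  violations <- validate_payload(payload)
  if (length(violations) > 0L) {
    stop("station '", station$center_id, "' returned a non-conformant payload: ",
         paste(violations, collapse = "; "), call. = FALSE)
  }
  structure(payload, class = "local_result")
}

#' Run a train across stations and combine the local results
#'
#' The master step of the federated computation: one local result per
#' station, then the cross-center combination — the mean ratio (by default
#' the unweighted arithmetic mean over centers with a defined ratio, the
#' benchmark-style reading of the audit's mean line; `mean_mode = "pooled"`
#' divides summed numerators by summed denominators instead), the expected
#' events per center (mean ratio times the center's denominator) and each
#' center's rate-of-mean (its ratio divided by the mean ratio). Centers
#' with undefined ratios are excluded from the mean with a message.
#'
#' @param stations list of [host_station()] results (at least one).
#' @param train a [build_train()] result.
#' @param mean_mode `"unweighted"` (default) or `"pooled"`.
#' @return object of class `global_result` with elements `indicator_id`,
#'   `local_results`, `mean_ratio`, `mean_mode`, `per_center_expected_events`,
#'   `per_center_rate_of_mean`.
#' @export
run_federated <- function(stations, train, mean_mode = c("unweighted", "pooled")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(length(stations) >= 1L)
  locals <- lapply(stations, run_train, train = train)
  ratios <- vapply(locals, function(x) x$ratio, numeric(1L))
  centers <- vapply(locals, function(x) x$center_id, character(1L))
  defined <- !is.na(ratios)
  if (!any(defined)) stop("no computable centers", call. = FALSE)
  if (any(!defined)) {
    message("excluded from the mean (undefined ratio): ",
            paste(centers[!defined], collapse = ", "))
  }
  mean_ratio <- if (mean_mode == "unweighted") {
    mean(ratios[defined])
  } else {
    num <- sum(vapply(locals[defined], function(x) x$numerator, numeric(1L)))
    den <- sum(vapply(locals[defined], function(x) x$denominator, numeric(1L)))
    num / den
  }
  dens <- vapply(locals, function(x) as.numeric(x$denominator), numeric(1L))
  expected <- ifelse(is.na(dens), NA_real_, mean_ratio * dens)
  rate_of_mean <- ratios / mean_ratio
  names(expected) <- centers
  names(rate_of_mean) <- centers
  structure(list(indicator_id = train$indicator_spec$indicator_id,
                 local_results = locals,
                 mean_ratio = mean_ratio,
                 mean_mode = mean_mode,
                 per_center_expected_events = expected,
                 per_center_rate_of_mean = rate_of_mean),
            class = "global_result")
}

#' @export
print.global_result <- function(x, ...) {
  cat(sprintf("<global_result> %s over %d center(s); mean ratio %.4f (%s)\n",
              x$indicator_id, length(x$local_results), x$mean_ratio, x$mean_mode))
  for (lr in x$local_results) print(lr)
  invisible(x)
}

#' Write a global result (or several) to JSON
#'
#' The JSON carries only aggregate fields: the per-center local results and
#' the combination statistics.
#'
#' @param globals named list of `global_result` objects (names are used as
#'   JSON keys) or a single `global_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_global_results <- function(globals, path) {
  if (inherits(globals, "global_result")) {
    globals <- stats::setNames(list(globals), globals$indicator_id)
  }
  out <- lapply(globals, function(g) {
    list(indicator_id = g$indicator_id,
         mean_ratio = g$mean_ratio,
         mean_mode = g$mean_mode,
         local_results = lapply(g$local_results, unclass),
         per_center_expected_events = as.list(g$per_center_expected_events),
         per_center_rate_of_mean = as.list(g$per_center_rate_of_mean))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read global results back from JSON
#'
#' @param path JSON written by [write_global_results()].
#' @return named list of `global_result` objects.
#' @export
read_global_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(g) {
    locals <- lapply(g$local_results, function(lr) {
      lr$ratio <- if (is.null(lr$ratio)) NA_real_ else lr$ratio
      lr$denominator <- if (is.null(lr$denominator)) NA_integer_ else lr$denominator
      lr$numerator <- if (is.null(lr$numerator)) NA_integer_ else lr$numerator
      structure(lr, class = "local_result")
    })
    structure(list(indicator_id = g$indicator_id,
                   local_results = locals,
                   mean_ratio = g$mean_ratio,
                   mean_mode = g$mean_mode,
                   per_center_expected_events =
                     unlist_keep_names(g$per_center_expected_events),
                   per_center_rate_of_mean =
                     unlist_keep_names(g$per_center_rate_of_mean)),
              class = "global_result")
  })
}

unlist_keep_names <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1L))
}
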