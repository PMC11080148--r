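# Fixtures are built in code: small hand-written tables for exact checks,
# generator configs for larger ones.

# a three-record table covering both localizations, a referred patient and
# a missing neoadjuvant date
tiny_table <- function(center_id = "demo") {
  records <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    hospital_id = center_id,
    tumor_localization = c("colon", "rectum", "rectum"),
    referred = c(FALSE, FALSE, TRUE),
    date_of_diagnosis = as.Date(c("2021-01-10", "2021-02-01", "2021-03-01")),
    date_neoadjuvant_start = as.Date(c(NA, "2021-02-20", NA)),
    date_of_surgery = as.Date(c("2021-02-10", "2021-04-15", "2021-03-20")),
    resection_type = c("sigmoid-resection", "low-anterior-resection",
                       "abdominoperineal-resection"),
    age = c(70L, 61L, 55L),
    bmi = c(27.4, 24.1, 31.0),
    charlson_score = c(1L, 0L, 3L),
    asa_class = c(2L, 1L, 3L),
    preop_tumor_complication = c(FALSE, TRUE, FALSE),
    postop_complication = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  flat_table(center_id, records)
}

# quota config mirroring the small simulated center: 40 patients, colon
# cohort 10 with 7 short waits, rectum cohort 7 with 4 complications
center2_quota_config <- function(seed = 11L) {
  generator_config("center2", 40L, seed = seed,
                   quota_counts = list(colon = c(10L, 7L), rectum = c(7L, 4L)))
}

center1_quota_config <- function(seed = 12L) {
  generator_config("center1", 4699L, seed = seed,
                   quota_counts = list(colon = c(546L, 546L),
                                       rectum = c(4153L, 2144L)))
}

# random valid table for property-style round trips
random_table <- function(seed, n = NULL) {
  cfg <- generator_config(paste0("rt", seed),
                          n %||% sample.int(30L, 1L),
                          seed = seed,
                          rectum_fraction = stats::runif(1),
                          referred_fraction = stats::runif(1, 0, 0.5),
                          neoadjuvant_fraction = stats::runif(1))
  generate_center(cfg)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

shipped_query <- function(indicator_id) {
  paste(readLines(system.file("queries", paste0(indicator_id, ".rq"),
                              package = "fedqi"), warn = FALSE),
        collapse = "\n")
}

# independent base-R oracle for the indicator counts, straight off the
# flat table (no RDF, no SPARQL, no package indicator code)
oracle_counts <- function(table, indicator_id, localization,
                          threshold = 35L, exclude_referred = TRUE) {
  r <- table$records
  keep <- r$tumor_localization == localization
  if (exclude_referred) keep <- keep & !r$referred
  r <- r[keep & !is.na(r$date_of_diagnosis), , drop = FALSE]
  if (indicator_id == "qi2b") {
    therapy <- ifelse(is.na(r$date_neoadjuvant_start),
                      as.integer(r$date_of_surgery),
                      pmin(as.integer(r$date_neoadjuvant_start),
                           as.integer(r$date_of_surgery)))
    num <- sum(therapy - as.integer(r$date_of_diagnosis) < threshold)
  } else {
    num <- sum(r$postop_complication)
  }
  c(denominator = nrow(r), numerator = as.integer(num))
}

# python rdflib as an independent RDF/SPARQL oracle: parse a Turtle file,
# run a query, return the row count (and optionally a named count of rows
# where a boolean variable is true)
rdflib_oracle <- function(ttl_path, query_path) {
  script <- paste(
    "import sys, rdflib, csv",
    "g = rdflib.Graph()",
    "g.parse(sys.argv[1], format='turtle')",
    "q = open(sys.argv[2]).read()",
    "res = g.query(q)",
    "w = csv.writer(sys.stdout)",
    "w.writerow([str(v) for v in res.vars])",
    "for row in res:",
    "    w.writerow(['' if v is None else str(v) for v in row])",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(ttl_path), shQuote(query_path)),
            stdout = TRUE, stderr = FALSE))
  read.csv(text = paste(out, collapse = "\n"), colClasses = "character")
}
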