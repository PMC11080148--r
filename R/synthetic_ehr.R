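# Synthetic per-center EHR flat tables for the colorectal-surgery indicator
# pipeline. Two sampling modes: Bernoulli marginals (probabilities) and quota
# (exact marginal counts via shuffled assignment), the latter needed to
# reconstruct published per-center count tables exactly.

#' Canonical flat-table column set
#'
#' Column order and types of a patient flat table: one row per patient with
#' the variables the two quality indicators use (identification, tumor
#' localization, referral, the three dates, resection type, and the case-mix
#' variables age, BMI, Charlson score, ASA class and pre/postoperative
#' complication flags).
#'
#' @return character vector of column names in canonical order.
#' @export
flat_table_columns <- function() {
  c("patient_id", "hospital_id", "tumor_localization", "referred",
    "date_of_diagnosis", "date_neoadjuvant_start", "date_of_surgery",
    "resection_type", "age", "bmi", "charlson_score", "asa_class",
    "preop_tumor_complication", "postop_complication")
}

# columns that may be empty (missing = absent)
optional_columns <- function() "date_neoadjuvant_start"

#' Construct a flat table
#'
#' A flat table bundles one center's patient records with its provenance
#' (the center id). Records are validated against the patient-record
#' invariants: unique patient ids, diagnosis date not after neoadjuvant start
#' (when present) nor after surgery, ASA class in 1..5, age >= 0, BMI > 0.
#'
#' @param center_id center label carried as provenance.
#' @param records data.frame with the columns of [flat_table_columns()].
#' @return object of class `flat_table` with elements `center_id`, `records`.
#' @export
flat_table <- function(center_id, records) {
  stopifnot(is.character(center_id), length(center_id) == 1L)
  cols <- flat_table_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("flat table missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, cols, drop = FALSE]
  validate_records(records)
  if (nrow(records) > 0L && !all(records$hospital_id == center_id)) {
    stop("all records must carry the table's hospital_id ('", center_id, "')", call. = FALSE)
  }
  structure(list(center_id = center_id, records = records), class = "flat_table")
}

validate_records <- function(r) {
  if (nrow(r) == 0L) return(invisible(TRUE))
  if (anyDuplicated(r$patient_id)) {
    stop("patient_id values must be unique within a table", call. = FALSE)
  }
  if (any(r$date_of_diagnosis > r$date_of_surgery)) {
    stop("date_of_diagnosis must not be after date_of_surgery", call. = FALSE)
  }
  has_neo <- !is.na(r$date_neoadjuvant_start)
  if (any(has_neo & (r$date_of_diagnosis > r$date_neoadjuvant_start |
                     r$date_neoadjuvant_start > r$date_of_surgery))) {
    stop("date_neoadjuvant_start must lie between diagnosis and surgery dates", call. = FALSE)
  }
  if (!all(r$asa_class %in% 1:5)) stop("asa_class must be in 1..5", call. = FALSE)
  if (any(r$age < 0)) stop("age must be >= 0", call. = FALSE)
  if (any(r$bmi <= 0)) stop("bmi must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.flat_table <- function(x, ...) {
  cat(sprintf("<flat_table> center '%s', %d patient record(s)\n",
              x$center_id, nrow(x$records)))
  invisible(x)
}

default_generator_dists <- function() {
  list(
    age = list(name = "normal", mean = 68, sd = 10, min = 18, max = 95, integer = TRUE),
    bmi = list(name = "lognormal", meanlog = log(26), sdlog = 0.15, min = 14, max = 55, digits = 1),
    charlson = list(name = "poisson", lambda = 1.5, max = 12),
    asa = list(name = "categorical", values = c(1L, 2L, 3L, 4L),
               probs = c(0.15, 0.55, 0.27, 0.03)),
    preop_complication = list(name = "bernoulli", prob = 0.2),
    waiting_time_days = list(name = "normal", mean = 28, sd = 14, min = 0, max = 120,
                             integer = TRUE)
  )
}

#' Build a synthetic-cohort generator configuration
#'
#' Defines one center's cohort: its size and either Bernoulli marginal
#' probabilities or exact quota counts. In quota mode, `quota_counts` is a
#' named list, one entry per tumor localization, each `c(denominator,
#' numerator)`; the denominator is the number of non-referred records with
#' that localization and the numerator is the count of indicator events in
#' that group — short waiting time (< 5 weeks) for `colon`, postoperative
#' complication for `rectum`, mirroring the audit's per-localization report
#' columns. Records beyond the quota denominators are generated as referred,
#' so they enter the table but not the indicator cohorts.
#'
#' Age, BMI, Charlson score, ASA class, preoperative complications and
#' waiting time are drawn from distribution specs (see [sample_dist()]);
#' defaults are plausible fixtures for a colorectal-surgery population, not
#' estimates from any real registry, and are also shipped as
#' `inst/extdata/generator_defaults.json`.
#'
#' @param center_id label stamped on every record as `hospital_id`.
#' @param n_patients number of records to generate.
#' @param seed integer seed; every stochastic call requires one explicitly.
#' @param rectum_fraction probability a (non-quota) record is a rectum case.
#' @param referred_fraction probability a Bernoulli-mode record is referred.
#' @param neoadjuvant_fraction probability a record receives neoadjuvant
#'   therapy before surgery.
#' @param complication_prob probability of a postoperative complication for
#'   records whose complication status is not fixed by a quota.
#' @param short_wait_fraction optional probability that waiting time is under
#'   35 days; when given it overrides `waiting_time_days` by drawing short
#'   waits uniformly from 7..34 days and long waits from 35..90 days.
#' @param quota_counts optional exact-marginal spec, see above; `NULL` for
#'   Bernoulli mode.
#' @param waiting_time_days,age,bmi,charlson,asa,preop_complication
#'   distribution specs; `NULL` uses the shipped defaults.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(center_id, n_patients, seed,
                             rectum_fraction = 0.35,
                             referred_fraction = 0.1,
                             neoadjuvant_fraction = 0.25,
                             complication_prob = 0.3,
                             short_wait_fraction = NULL,
                             quota_counts = NULL,
                             waiting_time_days = NULL,
                             age = NULL, bmi = NULL, charlson = NULL,
                             asa = NULL, preop_complication = NULL) {
  defaults <- default_generator_dists()
  cfg <- list(
    center_id = as.character(center_id),
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    rectum_fraction = rectum_fraction,
    referred_fraction = referred_fraction,
    neoadjuvant_fraction = neoadjuvant_fraction,
    complication_prob = complication_prob,
    short_wait_fraction = short_wait_fraction,
    quota_counts = quota_counts,
    waiting_time_days = waiting_time_days %||% defaults$waiting_time_days,
    age = age %||% defaults$age,
    bmi = bmi %||% defaults$bmi,
    charlson = charlson %||% defaults$charlson,
    asa = asa %||% defaults$asa,
    preop_complication = preop_complication %||% defaults$preop_complication
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_generator_config <- function(cfg) {
  check_prob <- function(field) {
    v <- cfg[[field]]
    if (is.null(v)) return(invisible(NULL))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("configuration error in '%s': must be a probability in [0,1]", field),
           call. = FALSE)
    }
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L) {
    stop("configuration error in 'n_patients': must be a non-negative integer", call. = FALSE)
  }
  if (is.na(cfg$seed)) {
    stop("configuration error in 'seed': an explicit integer seed is required", call. = FALSE)
  }
  for (f in c("rectum_fraction", "referred_fraction", "neoadjuvant_fraction",
              "complication_prob", "short_wait_fraction")) {
    check_prob(f)
  }
  # zero-size draws exercise each distribution spec without touching the RNG
  for (f in c("waiting_time_days", "age", "bmi", "charlson", "asa",
              "preop_complication")) {
    sample_dist(cfg[[f]], 0L, field = f)
  }
  if (!is.null(cfg$quota_counts)) {
    qc <- cfg$quota_counts
    if (!is.list(qc) || is.null(names(qc)) || any(names(qc) == "")) {
      stop("configuration error in 'quota_counts': must be a named list keyed by localization",
           call. = FALSE)
    }
    bad_loc <- setdiff(names(qc), c("colon", "rectum"))
    if (length(bad_loc) > 0L) {
      stop("configuration error in 'quota_counts': unknown localization '",
           bad_loc[1L], "'", call. = FALSE)
    }
    for (loc in names(qc)) {
      v <- qc[[loc]]
      if (length(v) != 2L || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
        stop(sprintf(
          "configuration error in 'quota_counts': entry '%s' must be two non-negative integers (denominator, numerator)",
          loc), call. = FALSE)
      }
      if (v[2L] > v[1L]) {
        stop(sprintf("quota infeasible: '%s' numerator %d exceeds denominator %d",
                     loc, as.integer(v[2L]), as.integer(v[1L])), call. = FALSE)
      }
    }
    total <- sum(vapply(qc, function(v) as.integer(v[1L]), integer(1L)))
    if (total > cfg$n_patients) {
      stop(sprintf("quota infeasible: quota denominators sum to %d but n_patients is %d",
                   total, cfg$n_patients), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a generator configuration from JSON
#'
#' The JSON fields mirror the arguments of [generator_config()];
#' `quota_counts` is an object mapping localization to a two-element array
#' `[denominator, numerator]`. A JSON-schema document describing the format
#' ships as `inst/extdata/generator_config_schema.json`.
#'
#' @param path path to a JSON config file.
#' @return object of class `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  required <- c("center_id", "n_patients", "seed")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0L) {
    stop("configuration error: missing required field '", miss[1L], "' in ", path,
         call. = FALSE)
  }
  allowed <- names(formals(generator_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop("configuration error: unknown field '", unknown[1L], "' in ", path, call. = FALSE)
  }
  do.call(generator_config, raw)
}

# waiting time in whole days for records whose short-wait status is fixed
draw_wait_given_short <- function(short) {
  n <- length(short)
  w <- integer(n)
  n_short <- sum(short)
  w[short] <- 7L + sample.int(28L, n_short, replace = TRUE) - 1L     # 7..34
  w[!short] <- 35L + sample.int(56L, n - n_short, replace = TRUE) - 1L # 35..90
  w
}

draw_wait_free <- function(cfg, n) {
  if (!is.null(cfg$short_wait_fraction)) {
    draw_wait_given_short(stats::runif(n) < cfg$short_wait_fraction)
  } else {
    w <- sample_dist(cfg$waiting_time_days, n, field = "waiting_time_days")
    as.integer(pmax(0, round(w)))
  }
}

resection_types <- function(localization) {
  colon_types <- c("right-hemicolectomy", "left-hemicolectomy", "sigmoid-resection")
  rectum_types <- c("low-anterior-resection", "abdominoperineal-resection")
  out <- character(length(localization))
  is_rect <- localization == "rectum"
  out[is_rect] <- sample(rectum_types, sum(is_rect), replace = TRUE)
  out[!is_rect] <- sample(colon_types, sum(!is_rect), replace = TRUE)
  out
}

#' Generate one center's synthetic flat table
#'
#' Deterministic given the configuration (which carries its own seed): the
#' same config always produces a byte-identical serialized table. In quota
#' mode the marginal counts match `quota_counts` exactly, with events
#' assigned by shuffling within each localization group.
#'
#' Waiting time is realized as an integer day offset from the diagnosis
#' date to the first therapy: when a record receives neoadjuvant therapy its
#' start date sits at that offset and surgery follows 21--70 days later;
#' otherwise surgery itself sits at the offset.
#'
#' @param config a [generator_config()].
#' @return a [flat_table()] with exactly `n_patients` records.
#' @export
generate_center <- function(config) {
  validate_generator_config(config)
  n <- config$n_patients
  if (n == 0L) {
    return(flat_table(config$center_id, empty_records()))
  }
  withr::with_seed(config$seed, generate_center_impl(config, n))
}

generate_center_impl <- function(cfg, n) {
  if (!is.null(cfg$quota_counts)) {
    parts <- lapply(names(cfg$quota_counts), function(loc) {
      v <- as.integer(cfg$quota_counts[[loc]])
      n_q <- v[1L]; k <- v[2L]
      event <- sample(c(rep(TRUE, k), rep(FALSE, n_q - k)))  # shuffled assignment
      if (loc == "colon") {
        data.frame(tumor_localization = rep(loc, n_q), referred = FALSE,
                   short_wait = event,
                   postop_complication = stats::runif(n_q) < cfg$complication_prob)
      } else {
        data.frame(tumor_localization = rep(loc, n_q), referred = FALSE,
                   short_wait = NA, postop_complication = event)
      }
    })
    n_extra <- n - sum(vapply(parts, nrow, integer(1L)))
    if (n_extra > 0L) {
      parts <- c(parts, list(data.frame(
        tumor_localization = ifelse(stats::runif(n_extra) < cfg$rectum_fraction,
                                    "rectum", "colon"),
        referred = TRUE,
        short_wait = NA,
        postop_complication = stats::runif(n_extra) < cfg$complication_prob
      )))
    }
    core <- do.call(rbind, parts)
  } else {
    core <- data.frame(
      tumor_localization = ifelse(stats::runif(n) < cfg$rectum_fraction, "rectum", "colon"),
      referred = stats::runif(n) < cfg$referred_fraction,
      short_wait = NA,
      postop_complication = stats::runif(n) < cfg$complication_prob
    )
  }

  wait <- integer(n)
  fixed <- !is.na(core$short_wait)
  wait[fixed] <- draw_wait_given_short(core$short_wait[fixed])
  wait[!fixed] <- draw_wait_free(cfg, sum(!fixed))

  diagnosis <- as.Date("2021-01-01") + (sample.int(365L, n, replace = TRUE) - 1L)
  first_therapy <- diagnosis + wait
  neo <- stats::runif(n) < cfg$neoadjuvant_fraction
  neo_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  surgery <- first_therapy
  neo_gap <- 21L + sample.int(50L, n, replace = TRUE) - 1L  # 21..70 days
  neo_date[neo] <- first_therapy[neo]
  surgery[neo] <- first_therapy[neo] + neo_gap[neo]

  records <- data.frame(
    patient_id = sprintf("%s-%05d", cfg$center_id, seq_len(n)),
    hospital_id = cfg$center_id,
    tumor_localization = core$tumor_localization,
    referred = core$referred,
    date_of_diagnosis = diagnosis,
    date_neoadjuvant_start = neo_date,
    date_of_surgery = surgery,
    resection_type = resection_types(core$tumor_localization),
    age = as.integer(sample_dist(cfg$age, n, "age")),
    bmi = as.numeric(sample_dist(cfg$bmi, n, "bmi")),
    charlson_score = as.integer(sample_dist(cfg$charlson, n, "charlson")),
    asa_class = as.integer(sample_dist(cfg$asa, n, "asa")),
    preop_tumor_complication = as.logical(sample_dist(cfg$preop_complication, n,
                                                      "preop_complication")),
    postop_complication = core$postop_complication,
    stringsAsFactors = FALSE
  )
  flat_table(cfg$center_id, records)
}

empty_records <- function() {
  data.frame(
    patient_id = character(), hospital_id = character(),
    tumor_localization = character(), referred = logical(),
    date_of_diagnosis = as.Date(character()),
    date_neoadjuvant_start = as.Date(character()),
    date_of_surgery = as.Date(character()),
    resection_type = character(), age = integer(), bmi = numeric(),
    charlson_score = integer(), asa_class = integer(),
    preop_tumor_complication = logical(), postop_complication = logical(),
    stringsAsFactors = FALSE
  )
}
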