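# CSV serialization of flat tables: UTF-8, comma-delimited, header row,
# ISO-8601 dates, empty string = missing, booleans as "yes"/"no".

bool_to_yesno <- function(x) ifelse(is.na(x), "", ifelse(x, "yes", "no"))

yesno_to_bool <- function(x) {
  out <- rep(NA, length(x))
  out[x == "yes"] <- TRUE
  out[x == "no"] <- FALSE
  out
}

#' Write a flat table to CSV
#'
#' Columns follow [flat_table_columns()]; dates are ISO-8601, booleans
#' "yes"/"no", missing values empty cells. The center id travels in the
#' `hospital_id` column of every row.
#'
#' @param table a [flat_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(table, path) {
  stopifnot(inherits(table, "flat_table"))
  r <- table$records
  out <- data.frame(
    patient_id = r$patient_id,
    hospital_id = r$hospital_id,
    tumor_localization = r$tumor_localization,
    referred = bool_to_yesno(r$referred),
    date_of_diagnosis = format(r$date_of_diagnosis, "%Y-%m-%d"),
    date_neoadjuvant_start = ifelse(is.na(r$date_neoadjuvant_start), "",
                                    format(r$date_neoadjuvant_start, "%Y-%m-%d")),
    date_of_surgery = format(r$date_of_surgery, "%Y-%m-%d"),
    resection_type = r$resection_type,
    age = r$age,
    bmi = r$bmi,
    charlson_score = r$charlson_score,
    asa_class = r$asa_class,
    preop_tumor_complication = bool_to_yesno(r$preop_tumor_complication),
    postop_complication = bool_to_yesno(r$postop_complication),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
                   eol = "\n")
  invisible(path)
}

parse_column <- function(x, col, parser, required = TRUE) {
  blank <- is.na(x) | x == ""
  if (required && any(blank)) {
    stop(sprintf("malformed row %d, column '%s': value is missing", which(blank)[1L], col),
         call. = FALSE)
  }
  out <- parser(x)
  bad <- which(!blank & is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("malformed row %d, column '%s': cannot parse value '%s'",
                 bad[1L], col, x[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read a flat table from CSV
#'
#' Inverse of [write_flat_table()]: `read_flat_table(write_flat_table(t))`
#' reproduces `t` field for field. Schema problems are reported by name:
#' a missing required column names the column, an unparseable cell names its
#' row index and column.
#'
#' @param path CSV file path.
#' @param center_id optional center label; defaults to the `hospital_id`
#'   value found in the file (required for empty files).
#' @return a [flat_table()].
#' @export
read_flat_table <- function(path, center_id = NULL) {
  if (!file.exists(path)) stop("flat table file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                         check.names = FALSE)
  miss <- setdiff(flat_table_columns(), names(raw))
  if (length(miss) > 0L) {
    stop("missing required column '", miss[1L], "' in ", path, call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    if (is.null(center_id)) stop("empty flat table file needs an explicit center_id",
                                 call. = FALSE)
    return(flat_table(center_id, empty_records()))
  }
  as_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  as_int <- function(x) suppressWarnings(as.integer(x))
  as_num <- function(x) suppressWarnings(as.numeric(x))
  records <- data.frame(
    patient_id = parse_column(raw$patient_id, "patient_id", identity),
    hospital_id = parse_column(raw$hospital_id, "hospital_id", identity),
    tumor_localization = parse_column(raw$tumor_localization, "tumor_localization",
                                      function(x) ifelse(x %in% c("colon", "rectum"), x, NA)),
    referred = parse_column(raw$referred, "referred", yesno_to_bool),
    date_of_diagnosis = parse_column(raw$date_of_diagnosis, "date_of_diagnosis", as_date),
    date_neoadjuvant_start = parse_column(raw$date_neoadjuvant_start,
                                          "date_neoadjuvant_start", as_date,
                                          required = FALSE),
    date_of_surgery = parse_column(raw$date_of_surgery, "date_of_surgery", as_date),
    resection_type = parse_column(raw$resection_type, "resection_type", identity),
    age = parse_column(raw$age, "age", as_int),
    bmi = parse_column(raw$bmi, "bmi", as_num),
    charlson_score = parse_column(raw$charlson_score, "charlson_score", as_int),
    asa_class = parse_column(raw$asa_class, "asa_class", as_int),
    preop_tumor_complication = parse_column(raw$preop_tumor_complication,
                                            "preop_tumor_complication", yesno_to_bool),
    postop_complication = parse_column(raw$postop_complication, "postop_complication",
                                       yesno_to_bool),
    stringsAsFactors = FALSE
  )
  flat_table(center_id %||% records$hospital_id[1L], records)
}
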