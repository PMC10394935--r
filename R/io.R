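#' Read and write patient records
#'
#' Patient JSON is an object `{"patient_id", "age", "sex", "diagnosis",
#' "blood_group", "status", "facts": {...}}`. Batch cohort CSV has one row
#' per patient with the structured columns plus one column per fact; booleans
#' are serialized `true`/`false`, unknown values as empty cells.
#'
#' @param path File path.
#' @return `read_patient()` returns an [patient_record()].
#' @export
read_patient <- function(path) {
  x <- jsonlite::read_json(path)
  .patient_from_list(x)
}

.patient_from_list <- function(x) {
  if (is.null(x$patient_id)) stop("patient JSON missing 'patient_id'")
  facts <- lapply(x$facts, function(v) if (is.null(v)) NA else v)
  patient_record(
    patient_id = x$patient_id,
    age = if (is.null(x$age)) NA_real_ else as.numeric(x$age),
    sex = if (is.null(x$sex)) NA_character_ else x$sex,
    diagnosis = if (is.null(x$diagnosis)) NA_character_ else x$diagnosis,
    blood_group = if (is.null(x$blood_group)) NULL else x$blood_group,
    status = if (is.null(x$status)) "referred" else x$status,
    facts = if (is.null(facts)) list() else facts
  )
}

#' @rdname read_patient
#' @param record An [patient_record()].
#' @export
write_patient <- function(record, path) {
  stopifnot(inherits(record, "ltx_patient"))
  x <- list(patient_id = record$patient_id)
  if (!is.na(record$age)) x$age <- record$age
  if (!is.na(record$sex)) x$sex <- record$sex
  if (!is.na(record$diagnosis)) x$diagnosis <- record$diagnosis
  if (!is.null(record$blood_group)) x$blood_group <- format(record$blood_group)
  x$status <- record$status
  x$facts <- record$facts
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

.fmt_cell <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) ""
  else if (is.logical(v)) if (v) "true" else "false"
  else as.character(v)
}

#' @rdname read_patient
#' @param records List of [patient_record()]s.
#' @export
write_cohort_csv <- function(records, path) {
  fact_names <- unique(unlist(lapply(records, function(r) names(r$facts))))
  header <- c("patient_id", "age", "sex", "diagnosis", "blood_group", "status",
              fact_names)
  rows <- lapply(records, function(r) {
    base <- c(r$patient_id, .fmt_cell(r$age), .fmt_cell(r$sex),
              .fmt_cell(r$diagnosis),
              if (is.null(r$blood_group)) "" else format(r$blood_group),
              r$status)
    cells <- vapply(fact_names, function(f) .fmt_cell(r$facts[[f]]), character(1))
    c(base, cells)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- header
  utils::write.csv(m, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.parse_cell <- function(s) {
  if (is.na(s) || s == "") return(NA)
  if (s %in% c("true", "TRUE", "True")) return(TRUE)
  if (s %in% c("false", "FALSE", "False")) return(FALSE)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

#' @rdname read_patient
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!("patient_id" %in% names(df))) stop("cohort CSV missing 'patient_id'")
  structured <- c("patient_id", "age", "sex", "diagnosis", "blood_group",
                  "status")
  fact_cols <- setdiff(names(df), structured)
  lapply(seq_len(nrow(df)), function(i) {
    facts <- lapply(fact_cols, function(f) .parse_cell(df[[f]][i]))
    names(facts) <- fact_cols
    facts <- facts[!vapply(facts, function(v) length(v) == 1L && is.na(v),
                           logical(1))]
    g <- function(col, default = NA_character_) {
      if (!(col %in% names(df)) || is.na(df[[col]][i]) || df[[col]][i] == "")
        default
      else df[[col]][i]
    }
    patient_record(
      patient_id = df$patient_id[i],
      age = {a <- g("age"); if (is.na(a)) NA_real_ else as.numeric(a)},
      sex = g("sex"),
      diagnosis = g("diagnosis"),
      blood_group = {b <- g("blood_group"); if (is.na(b)) NULL else b},
      status = g("status", "referred"),
      facts = facts
    )
  })
}

#' Read a labelled-predictions table
#'
#' CSV with columns `patient_id`, `predicted`, `actual` (booleans as
#' `true`/`false` or `TRUE`/`FALSE`).
#'
#' @param path File path.
#' @return Data frame with logical columns `predicted` and `actual`.
#' @export
read_predictions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "predicted", "actual")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("predictions CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  to_lgl <- function(v) {
    out <- tolower(as.character(v)) == "true"
    out[!(tolower(as.character(v)) %in% c("true", "false"))] <- NA
    out
  }
  df$predicted <- to_lgl(df$predicted)
  df$actual <- to_lgl(df$actual)
  if (anyNA(df$predicted) || anyNA(df$actual)) {
    stop("predictions CSV contains non-boolean predicted/actual values")
  }
  df
}
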