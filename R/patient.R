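#' Patient status vocabulary
#'
#' The five statuses a lung-transplant candidate moves through, from referral
#' to transplantation.
#'
#' @return Character vector of the five legal statuses, in workflow order.
#' @export
patient_statuses <- function() {
  c("referred", "preassessment", "referred_to_committee",
    "waiting_list", "transplanted")
}

.check_status <- function(status) {
  if (!is.character(status) || length(status) != 1L ||
      !(status %in% patient_statuses())) {
    stop("invalid patient status: ", deparse(status),
         " (legal: ", paste(patient_statuses(), collapse = ", "), ")")
  }
  status
}

#' Patient record
#'
#' A candidate's demographic fields plus an open fact map consumed by the
#' inference engine. A fact that is absent, or present with value `NA`, is
#' *unknown* — three-valued logic distinguishes it from `FALSE`.
#'
#' @param patient_id Opaque identifier string.
#' @param age Age in years (finite, non-negative), or `NA` if unknown.
#' @param sex `"male"`, `"female"`, or `NA`.
#' @param diagnosis Diagnosis code string (e.g. `"COPD"`), or `NA`.
#' @param blood_group An [blood_group()] object, a string such as `"O+"`, or
#'   `NULL` if unknown.
#' @param status One of [patient_statuses()].
#' @param facts Named list of fact values (logical, numeric, or character
#'   scalars; `NA` means unknown). Names must be unique.
#' @param categories Optional named character vector grouping fact names into
#'   schema categories.
#' @return An object of class `ltx_patient`.
#' @export
patient_record <- function(patient_id, age = NA_real_, sex = NA_character_,
                           diagnosis = NA_character_, blood_group = NULL,
                           status = "referred", facts = list(),
                           categories = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            nzchar(patient_id))
  if (!is.na(age)) {
    age <- as.numeric(age)
    if (!is.finite(age) || age < 0) stop("age must be finite and >= 0, got ", age)
  }
  if (!is.na(sex)) sex <- match.arg(sex, c("male", "female"))
  if (is.character(blood_group)) blood_group <- parse_blood_group(blood_group)
  if (!is.null(blood_group) && !inherits(blood_group, "ltx_blood_group")) {
    stop("blood_group must be an ltx_blood_group, a string, or NULL")
  }
  .check_status(status)
  if (!is.list(facts)) stop("facts must be a named list")
  if (length(facts) > 0L) {
    nm <- names(facts)
    if (is.null(nm) || any(!nzchar(nm))) stop("all facts must be named")
    if (anyDuplicated(nm)) {
      stop("duplicate fact names: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    }
  }
  structure(
    list(patient_id = patient_id, age = age, sex = sex, diagnosis = diagnosis,
         blood_group = blood_group, status = status, facts = facts,
         categories = categories, audit = list()),
    class = "ltx_patient"
  )
}

#' @export
print.ltx_patient <- function(x, ...) {
  cat("<patient ", x$patient_id, "> status=", x$status,
      if (!is.null(x$blood_group)) paste0(" blood=", format(x$blood_group)),
      if (!is.na(x$age)) paste0(" age=", x$age),
      if (!is.na(x$diagnosis)) paste0(" dx=", x$diagnosis),
      " facts=", length(x$facts), "\n", sep = "")
  invisible(x)
}

#' Merge a record's structured fields into its fact map
#'
#' The engine consumes a flat fact map; `age`, `sex`, `diagnosis`, `status`
#' and `blood_group` are exposed as facts of the same name (explicit entries
#' in `facts` win).
#'
#' @param record An [patient_record()].
#' @return Named list of facts.
#' @export
record_facts <- function(record) {
  stopifnot(inherits(record, "ltx_patient"))
  base <- list()
  if (!is.na(record$age)) base$age <- record$age
  if (!is.na(record$sex)) base$sex <- record$sex
  if (!is.na(record$diagnosis)) base$diagnosis <- record$diagnosis
  if (!is.null(record$blood_group)) base$blood_group <- format(record$blood_group)
  base$status <- record$status
  utils::modifyList(base, record$facts)
}

#' Data schema
#'
#' An ordered list of data items, each with a value kind and a category. The
#' eight default category names are documented placeholders (the originating
#' study grouped its 63 candidate items into eight unnamed domains); replace
#' them freely.
#'
#' @param items Character vector of item names (unique).
#' @param kinds Character vector (recycled) of value kinds:
#'   `"number"`, `"boolean"`, or `"string"`.
#' @param categories Character vector (recycled) assigning each item to a
#'   category.
#' @return An object of class `ltx_schema` (a data frame with columns
#'   `item`, `kind`, `category`).
#' @export
data_schema <- function(items, kinds = "string", categories = "general") {
  stopifnot(is.character(items), length(items) > 0L)
  if (anyDuplicated(items)) {
    stop("duplicate schema items: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  kinds <- rep_len(kinds, length(items))
  bad <- setdiff(unique(kinds), c("number", "boolean", "string"))
  if (length(bad)) stop("unknown value kind(s): ", paste(bad, collapse = ", "))
  categories <- rep_len(categories, length(items))
  structure(
    data.frame(item = items, kind = kinds, category = categories,
               stringsAsFactors = FALSE),
    class = c("ltx_schema", "data.frame")
  )
}

#' Default referral data schema
#'
#' Covers the facts used by the bundled referral knowledge pack, grouped into
#' eight placeholder domains.
#'
#' @return An `ltx_schema`.
#' @export
default_schema <- function() {
  data_schema(
    items = c("age", "sex", "blood_group",
              "diagnosis", "diagnosis_confirmed", "disease_permitted",
              "ESLD", "survival_lt_50pct", "advanced_despite_treatment",
              "nyha_symptoms", "nyha_class",
              "fev1_pct", "FEV1_flag",
              "dyspnea_history",
              "recurrent_hospitalization",
              "status"),
    kinds = c("number", "string", "string",
              "string", "boolean", "boolean",
              "boolean", "boolean", "boolean",
              "string", "string",
              "number", "boolean",
              "boolean",
              "boolean",
              "string"),
    categories = c("demographics", "demographics", "demographics",
                   "diagnosis", "diagnosis", "diagnosis",
                   "disease_severity", "disease_severity", "disease_severity",
                   "functional_status", "functional_status",
                   "pulmonary_function", "pulmonary_function",
                   "symptoms",
                   "clinical_history",
                   "administrative")
  )
}

.kind_valid <- function(value, kind) {
  if (length(value) != 1L) return(FALSE)
  switch(kind,
    number  = is.numeric(value) && is.finite(value),
    boolean = is.logical(value) && !is.na(value),
    string  = is.character(value) && !is.na(value) && nzchar(value),
    FALSE)
}

#' Validate a record against a schema
#'
#' Each schema item is classified as `present-valid`, `present-invalid`
#' (present but of the wrong kind — never an exception), or `missing`
#' (absent or `NA`, i.e. unknown). Completeness is the fraction of items
#' present and valid.
#'
#' @param record An [patient_record()].
#' @param schema An [data_schema()].
#' @return An object of class `ltx_validation` with elements `items` (data
#'   frame: `item`, `category`, `status`), `missing` (character vector), and
#'   `completeness`.
#' @export
validate_record <- function(record, schema) {
  stopifnot(inherits(record, "ltx_patient"), inherits(schema, "ltx_schema"))
  if (nrow(schema) == 0L) stop("schema is empty")
  facts <- record_facts(record)
  status <- character(nrow(schema))
  for (i in seq_len(nrow(schema))) {
    v <- facts[[schema$item[i]]]
    status[i] <-
      if (is.null(v) || (length(v) == 1L && is.na(v))) "missing"
      else if (.kind_valid(v, schema$kind[i])) "present-valid"
      else "present-invalid"
  }
  items <- data.frame(item = schema$item, category = schema$category,
                      status = status, stringsAsFactors = FALSE)
  structure(
    list(items = items,
         missing = schema$item[status == "missing"],
         completeness = mean(status == "present-valid")),
    class = "ltx_validation"
  )
}

#' @export
print.ltx_validation <- function(x, ...) {
  cat("<validation> completeness=", sprintf("%.3f", x$completeness),
      " (", sum(x$items$status == "present-valid"), "/", nrow(x$items),
      " valid", sep = "")
  if (length(x$missing)) {
    cat("; missing: ", paste(x$missing, collapse = ", "), sep = "")
  }
  inv <- x$items$item[x$items$status == "present-invalid"]
  if (length(inv)) cat("; invalid: ", paste(inv, collapse = ", "), sep = "")
  cat(")\n")
  invisible(x)
}
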