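#' The six-point candidate-management workflow
#'
#' Candidate management is modelled as six sequential decision points over the
#' five patient statuses. Each point names the rule category whose decision
#' trees it runs, the status a record must hold on entry, the status proposed
#' on success, the boolean *stage fact* that carries the verdict, and what a
#' definite failure means (`remain` or `exit` with a reason). The default
#' configuration is:
#'
#' | # | point | category | entry | success |
#' |---|-------|----------|-------|---------|
#' | 1 | referral investigation (13 decision trees) | `referral_criteria` | referred | preassessment |
#' | 2 | initial assessment (2) | `initial_assessment` | preassessment | referred_to_committee |
#' | 3 | committee review | `committee` | referred_to_committee | waiting_list |
#' | 4 | waiting-list placement (1) | `waiting_list_placement` | referred_to_committee | waiting_list |
#' | 5 | follow-up (3, self-loop) | `follow_up` | waiting_list | waiting_list |
#' | 6 | donor-day selection (1) | `donor_selection` | waiting_list | transplanted |
#'
#' Points 3 and 4 share the `referred_to_committee -> waiting_list` edge
#' (committee approval and list placement are one status change). Point 5 is a
#' self-loop whose failure exits with reason `"delisted"`. `transplanted` is
#' terminal. The point names are configurable defaults — the original
#' six-point model's labels are not published.
#'
#' @return A `ltx_workflow` object: list of six decision points plus the legal
#'   status-transition edge set.
#' @export
default_workflow <- function() {
  pt <- function(index, name, category, entry, success, stage_fact,
                 on_failure = "remain", exit_reason = NA_character_) {
    list(index = index, name = name, category = category, entry = entry,
         success = success, stage_fact = stage_fact,
         on_failure = on_failure, exit_reason = exit_reason)
  }
  points <- list(
    pt(1L, "referral investigation", "referral_criteria",
       "referred", "preassessment", "referral_criteria_met"),
    pt(2L, "initial assessment", "initial_assessment",
       "preassessment", "referred_to_committee", "initial_assessment_passed"),
    pt(3L, "committee review", "committee",
       "referred_to_committee", "waiting_list", "committee_approved",
       on_failure = "exit", exit_reason = "rejected by committee"),
    pt(4L, "waiting-list placement", "waiting_list_placement",
       "referred_to_committee", "waiting_list", "listing_confirmed"),
    pt(5L, "follow-up", "follow_up",
       "waiting_list", "waiting_list", "follow_up_ok",
       on_failure = "exit", exit_reason = "delisted"),
    pt(6L, "donor-day selection", "donor_selection",
       "waiting_list", "transplanted", "donor_match_confirmed")
  )
  edges <- rbind(
    c("referred", "preassessment"),
    c("preassessment", "referred_to_committee"),
    c("referred_to_committee", "waiting_list"),
    c("waiting_list", "waiting_list"),      # follow-up self-loop
    c("waiting_list", "transplanted")
  )
  colnames(edges) <- c("from", "to")
  structure(list(points = points, edges = edges), class = "ltx_workflow")
}

#' Evaluate one decision point for a record
#'
#' Runs the pack's rules of the point's category (together with any
#' lower-indexed categories' derived facts already present in the record's
#' fact map) against the record and classifies the outcome by the stage fact:
#' definitely true is `passed` (proposing the point's success status),
#' definitely false is `failed`, unknown is `needs_data` (status unchanged,
#' data requests listed). The stage fact may equally be supplied directly as
#' an input fact — stages whose rule sections are empty extension points (the
#' bundled pack only ships referral rules) are then driven by recorded
#' clinical sign-off.
#'
#' @param record An [patient_record()]; its status must equal the point's
#'   entry status.
#' @param point One of the six points of a [default_workflow()], or its index.
#' @param pack An `ltx_pack`.
#' @param workflow A `ltx_workflow` (used when `point` is an index).
#' @return An `ltx_stage_outcome`: `outcome` (`"passed"`/`"failed"`/
#'   `"needs_data"`), `proposed_status`, `exit_reason`, `point`, and the full
#'   `inference` result.
#' @export
evaluate_stage <- function(record, point, pack, workflow = default_workflow()) {
  stopifnot(inherits(record, "ltx_patient"), inherits(pack, "ltx_pack"))
  if (is.numeric(point)) point <- workflow$points[[point]]
  if (record$status != point$entry) {
    stop("record '", record$patient_id, "' has status '", record$status,
         "' but decision point ", point$index, " (", point$name,
         ") requires entry status '", point$entry, "'")
  }
  sub <- pack
  sub$rules <- Filter(function(r) r$category == point$category, pack$rules)
  res <- infer(record, sub)
  v <- res$facts[[point$stage_fact]]
  outcome <-
    if (isTRUE(v)) "passed"
    else if (isFALSE(v)) "failed"
    else "needs_data"
  structure(
    list(outcome = outcome,
         proposed_status = if (outcome == "passed") point$success else record$status,
         exit_reason = if (outcome == "failed" && point$on_failure == "exit")
           point$exit_reason else NA_character_,
         point = point,
         patient_id = record$patient_id,
         inference = res),
    class = "ltx_stage_outcome"
  )
}

#' @export
print.ltx_stage_outcome <- function(x, ...) {
  cat("<stage ", x$point$index, " '", x$point$name, "'> ", x$outcome, sep = "")
  if (x$outcome == "passed") cat(" -> ", x$proposed_status, sep = "")
  if (!is.na(x$exit_reason)) cat(" (", x$exit_reason, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Advance a record on a stage outcome
#'
#' Applies a `passed` outcome's proposed status to the record, checking the
#' transition against the workflow's legal edge set, and appends a timestamped
#' entry (linked to the fired-rule trace) to the record's audit log.
#' `needs_data` leaves the record untouched; a `failed` outcome with an exit
#' policy marks the record as exited with the reason. `transplanted` is
#' terminal: any transition out of it is an error.
#'
#' @param record The [patient_record()] the outcome was produced for.
#' @param outcome An `ltx_stage_outcome` from [evaluate_stage()].
#' @param workflow A `ltx_workflow`.
#' @return The updated record.
#' @export
advance <- function(record, outcome, workflow = default_workflow()) {
  stopifnot(inherits(record, "ltx_patient"),
            inherits(outcome, "ltx_stage_outcome"))
  if (!identical(outcome$patient_id, record$patient_id)) {
    stop("outcome was produced for patient '", outcome$patient_id,
         "', not '", record$patient_id, "'")
  }
  if (outcome$outcome == "needs_data") return(record)
  if (outcome$outcome == "failed") {
    if (!is.na(outcome$exit_reason)) {
      record$exited <- TRUE
      record$exit_reason <- outcome$exit_reason
      record$audit <- c(record$audit, list(list(
        time = Sys.time(), point = outcome$point$index,
        from = record$status, to = record$status,
        event = paste0("exit: ", outcome$exit_reason),
        fired_rules = outcome$inference$fired$rule_id)))
    }
    return(record)
  }
  from <- record$status
  to <- outcome$proposed_status
  if (from == "transplanted") {
    stop("illegal transition: 'transplanted' is terminal")
  }
  legal <- any(workflow$edges[, "from"] == from & workflow$edges[, "to"] == to)
  if (!legal) {
    stop("illegal status transition: '", from, "' -> '", to, "'")
  }
  record$status <- to
  record$audit <- c(record$audit, list(list(
    time = Sys.time(), point = outcome$point$index,
    from = from, to = to, event = "advance",
    fired_rules = outcome$inference$fired$rule_id)))
  record
}

#' Cohort frequency report
#'
#' Status and blood-group composition of a cohort, with percentages to one
#' decimal place.
#'
#' @param records List of [patient_record()]s.
#' @return A data frame with columns `section` (`status`/`blood_group`),
#'   `value`, `count`, `pct`.
#' @export
cohort_report <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "ltx_patient")))
  n <- length(records)
  if (n == 0L) {
    return(data.frame(section = character(), value = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  statuses <- vapply(records, `[[`, character(1), "status")
  bgs <- vapply(records, function(r) {
    if (is.null(r$blood_group)) NA_character_ else format(r$blood_group)
  }, character(1))
  row_block <- function(section, values, levels) {
    tab <- table(factor(values, levels = levels))
    tab <- tab[tab > 0]
    data.frame(section = section, value = names(tab),
               count = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_block("status", statuses, patient_statuses()),
    row_block("blood_group", bgs[!is.na(bgs)], blood_groups())
  )
  rownames(out) <- NULL
  out
}
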