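#' Donor descriptor
#'
#' @param donor_id Identifier string.
#' @param blood_group An [blood_group()] or string such as `"O-"`.
#' @param attributes Optional named list of extra attributes.
#' @return An `ltx_donor`.
#' @export
donor_descriptor <- function(donor_id, blood_group, attributes = list()) {
  stopifnot(is.character(donor_id), length(donor_id) == 1L, nzchar(donor_id))
  if (is.character(blood_group)) blood_group <- parse_blood_group(blood_group)
  stopifnot(inherits(blood_group, "ltx_blood_group"))
  structure(list(donor_id = donor_id, blood_group = blood_group,
                 attributes = attributes),
            class = "ltx_donor")
}

#' @export
print.ltx_donor <- function(x, ...) {
  cat("<donor ", x$donor_id, "> blood=", format(x$blood_group), "\n", sep = "")
  invisible(x)
}

#' List waiting-list candidates compatible with a donor
#'
#' Only patients with status `waiting_list` are considered. Candidates are
#' ordered by compatibility exactness (identical ABO/Rh group first, then
#' merely compatible), then by waiting time (a numeric `waiting_days` fact,
#' longest first) when present, ties broken by `patient_id`.
#'
#' @param donor An [donor_descriptor()].
#' @param cohort List of [patient_record()]s.
#' @param policy An [compatibility_policy()]; the conservative default is
#'   identical-group with strict Rh.
#' @return A data frame with columns `patient_id`, `blood_group`, `match`
#'   (`"identical"`/`"compatible"`), `waiting_days`, and `rationale`; zero
#'   rows when no candidate is compatible.
#' @export
eligible_candidates <- function(donor, cohort,
                                policy = compatibility_policy()) {
  stopifnot(inherits(donor, "ltx_donor"), inherits(policy, "ltx_policy"))
  rows <- list()
  for (r in cohort) {
    stopifnot(inherits(r, "ltx_patient"))
    if (r$status != "waiting_list" || is.null(r$blood_group)) next
    if (!is_compatible(donor$blood_group, r$blood_group, policy)) next
    identical_grp <- donor$blood_group$abo == r$blood_group$abo &&
      donor$blood_group$rh == r$blood_group$rh
    wd <- r$facts$waiting_days
    wd <- if (is.null(wd) || !is.numeric(wd) || is.na(wd)) NA_real_ else wd
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = r$patient_id,
      blood_group = format(r$blood_group),
      match = if (identical_grp) "identical" else "compatible",
      waiting_days = wd,
      rationale = paste0("donor ", format(donor$blood_group), " -> recipient ",
                         format(r$blood_group), " (",
                         if (identical_grp) "identical group" else
                           paste0("ABO-compatible under ", policy$mode),
                         if (policy$rh_strict) ", Rh enforced" else "", ")"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(patient_id = character(), blood_group = character(),
                      match = character(), waiting_days = numeric(),
                      rationale = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$match != "identical",            # identical first
               -ifelse(is.na(out$waiting_days), -Inf, out$waiting_days),
               out$patient_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
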