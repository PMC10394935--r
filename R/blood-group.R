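#' Blood group (ABO/Rh)
#'
#' A blood group is one of the eight ABO/Rh combinations used in transplant
#' candidate records and donor descriptors: O+, O-, A+, A-, B+, B-, AB+, AB-.
#'
#' @param abo One of `"O"`, `"A"`, `"B"`, `"AB"`.
#' @param rh One of `"positive"`, `"negative"`.
#' @return An object of class `ltx_blood_group` with fields `abo` and `rh`.
#' @examples
#' blood_group("O", "positive")
#' parse_blood_group("AB-")
#' @export
blood_group <- function(abo, rh) {
  abo <- match.arg(abo, c("O", "A", "B", "AB"))
  rh <- match.arg(rh, c("positive", "negative"))
  structure(list(abo = abo, rh = rh), class = "ltx_blood_group")
}

#' Parse a blood-group string
#'
#' Accepts the eight canonical forms (`"O+"`, `"AB-"`, ...) and tolerates the
#' Unicode minus sign (U+2212), en dash, and "neg"/"pos" suffixes; the result
#' is normalised to the canonical ASCII form by [format()].
#'
#' @param text A single string.
#' @return An `ltx_blood_group`.
#' @export
parse_blood_group <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("blood group must be a single string, got: ", deparse(text))
  }
  raw <- text
  s <- toupper(trimws(text))
  # normalise unicode minus (U+2212), en dash (U+2013), hyphen variants
  s <- gsub("−|–|—", "-", s)
  s <- sub("NEG(ATIVE)?$", "-", s)
  s <- sub("POS(ITIVE)?$", "+", s)
  m <- regmatches(s, regexec("^(O|A|B|AB)\\s*([+-])$", s))[[1]]
  if (length(m) == 0L) {
    stop("unrecognized blood group: '", raw,
         "' (expected one of O+, O-, A+, A-, B+, B-, AB+, AB-)")
  }
  blood_group(m[2L], if (m[3L] == "+") "positive" else "negative")
}

#' @export
format.ltx_blood_group <- function(x, ...) {
  paste0(x$abo, if (x$rh == "positive") "+" else "-")
}

#' @export
print.ltx_blood_group <- function(x, ...) {
  cat("<blood group ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
as.character.ltx_blood_group <- function(x, ...) format(x)

#' All eight legal blood groups
#'
#' @return Character vector of the eight canonical blood-group strings.
#' @export
blood_groups <- function() {
  c("O+", "O-", "A+", "A-", "B+", "B-", "AB+", "AB-")
}

# donor ABO -> compatible recipient ABO groups (standard matrix)
.abo_recipients <- list(
  O  = c("O", "A", "B", "AB"),
  A  = c("A", "AB"),
  B  = c("B", "AB"),
  AB = c("AB")
)

#' Donor-recipient compatibility policy
#'
#' @param mode `"identical_only"` (same ABO group) or `"abo_compatible"`
#'   (standard matrix: O donates to all, A to A/AB, B to B/AB, AB to AB).
#' @param rh_strict If `TRUE`, an Rh-positive donor is only compatible with
#'   Rh-positive recipients (Rh-negative donors are universal for Rh).
#' @return An object of class `ltx_policy`.
#' @export
compatibility_policy <- function(mode = c("identical_only", "abo_compatible"),
                                 rh_strict = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.logical(rh_strict), length(rh_strict) == 1L, !is.na(rh_strict))
  structure(list(mode = mode, rh_strict = rh_strict), class = "ltx_policy")
}

#' Is a donor blood group compatible with a recipient?
#'
#' @param donor,recipient `ltx_blood_group` objects (or strings).
#' @param policy An [compatibility_policy()].
#' @return `TRUE`/`FALSE`.
#' @export
is_compatible <- function(donor, recipient, policy = compatibility_policy()) {
  if (is.character(donor)) donor <- parse_blood_group(donor)
  if (is.character(recipient)) recipient <- parse_blood_group(recipient)
  abo_ok <- switch(policy$mode,
    identical_only = donor$abo == recipient$abo,
    abo_compatible = recipient$abo %in% .abo_recipients[[donor$abo]]
  )
  rh_ok <- !policy$rh_strict ||
    donor$rh == "negative" || recipient$rh == "positive"
  abo_ok && rh_ok
}
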