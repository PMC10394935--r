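#' Rule conditions
#'
#' Antecedents of knowledge-pack rules are trees of atoms combined with
#' `all`/`any`/`not`. An atom compares one fact against an operand with one of
#' the comparators `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `in_set`. Evaluation is
#' three-valued (Kleene strong logic): a fact that is absent or `NA` evaluates
#' to *unknown*, and unknown propagates — `unknown AND true = unknown`,
#' `unknown AND false = false`, `unknown OR true = true`, `NOT unknown =
#' unknown`. A definite verdict therefore never changes when an unknown fact
#' later becomes known.
#'
#' @param fact Fact name (string).
#' @param op Comparator: `"eq"`, `"ne"`, `"lt"`, `"le"`, `"gt"`, `"ge"`,
#'   or `"in_set"`.
#' @param value Operand: a scalar, or a vector for `in_set`.
#' @return A condition node of class `ltx_condition`.
#' @name conditions
NULL

.comparators <- c("eq", "ne", "lt", "le", "gt", "ge", "in_set")

#' @rdname conditions
#' @export
cnd_atom <- function(fact, op, value) {
  stopifnot(is.character(fact), length(fact) == 1L, nzchar(fact))
  op <- match.arg(op, .comparators)
  if (op != "in_set" && length(value) != 1L) {
    stop("comparator '", op, "' needs a scalar operand")
  }
  structure(list(kind = "atom", fact = fact, op = op, value = value),
            class = "ltx_condition")
}

.cnd_composite <- function(kind, children) {
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "ltx_condition")) {
    children <- children[[1]]
  }
  ok <- vapply(children, inherits, logical(1), "ltx_condition")
  if (length(children) == 0L || !all(ok)) {
    stop("'", kind, "' needs one or more ltx_condition children")
  }
  structure(list(kind = kind, children = children), class = "ltx_condition")
}

#' @rdname conditions
#' @param ... Child conditions (or a single list of them).
#' @export
cnd_all <- function(...) .cnd_composite("and", list(...))

#' @rdname conditions
#' @export
cnd_any <- function(...) .cnd_composite("or", list(...))

#' @rdname conditions
#' @param x A condition to negate.
#' @export
cnd_not <- function(x) {
  stopifnot(inherits(x, "ltx_condition"))
  structure(list(kind = "not", children = list(x)), class = "ltx_condition")
}

# three-valued atom evaluation: TRUE / FALSE / NA (unknown)
.eval_atom <- function(node, facts) {
  v <- facts[[node$fact]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA)
  op <- node$op
  operand <- node$value
  if (op %in% c("lt", "le", "gt", "ge")) {
    if (!is.numeric(v) || !is.numeric(operand)) return(NA)  # not comparable
    return(switch(op, lt = v < operand, le = v <= operand,
                  gt = v > operand, ge = v >= operand))
  }
  if (op == "in_set") {
    return(isTRUE(any(vapply(operand, function(o) .scalar_eq(v, o), logical(1)))))
  }
  eq <- .scalar_eq(v, operand)
  if (op == "eq") eq else !eq
}

.scalar_eq <- function(a, b) {
  if (is.logical(a) || is.logical(b)) {
    return(is.logical(a) && is.logical(b) && identical(a, b))
  }
  if (is.numeric(a) && is.numeric(b)) return(isTRUE(a == b))
  if (is.character(a) && is.character(b)) return(identical(a, b))
  FALSE  # cross-kind equality is definite false, not unknown
}

#' Evaluate a condition over a fact map
#'
#' @param cond An `ltx_condition`.
#' @param facts Named list of fact values; absent or `NA` means unknown.
#' @return `TRUE`, `FALSE`, or `NA` (unknown).
#' @export
eval_condition <- function(cond, facts) {
  stopifnot(inherits(cond, "ltx_condition"))
  switch(cond$kind,
    atom = .eval_atom(cond, facts),
    # base R's logical ops already implement Kleene logic with NA
    and = {
      r <- TRUE
      for (ch in cond$children) r <- r & eval_condition(ch, facts)
      r
    },
    or = {
      r <- FALSE
      for (ch in cond$children) r <- r | eval_condition(ch, facts)
      r
    },
    not = !eval_condition(cond$children[[1]], facts),
    stop("unknown condition kind: ", cond$kind)
  )
}

#' Atoms of a condition
#'
#' @param cond An `ltx_condition`.
#' @return List of the atom nodes appearing in `cond` (depth-first).
#' @export
condition_atoms <- function(cond) {
  if (cond$kind == "atom") return(list(cond))
  unlist(lapply(cond$children, condition_atoms), recursive = FALSE)
}

#' Fact names referenced by a condition
#' @param cond An `ltx_condition`.
#' @return Character vector of distinct fact names.
#' @export
condition_facts <- function(cond) {
  unique(vapply(condition_atoms(cond), `[[`, character(1), "fact"))
}

# fact names of atoms that evaluate to unknown under `facts`
.blocking_facts <- function(cond, facts) {
  unique(vapply(
    Filter(function(a) is.na(.eval_atom(a, facts)), condition_atoms(cond)),
    `[[`, character(1), "fact"))
}

#' @export
format.ltx_condition <- function(x, ...) {
  switch(x$kind,
    atom = paste0(x$fact, " ", x$op, " ",
                  if (length(x$value) > 1L)
                    paste0("{", paste(x$value, collapse = ", "), "}")
                  else format(x$value)),
    and = paste0("(", paste(vapply(x$children, format, character(1)),
                            collapse = " AND "), ")"),
    or  = paste0("(", paste(vapply(x$children, format, character(1)),
                            collapse = " OR "), ")"),
    not = paste0("NOT ", format(x$children[[1]]))
  )
}

#' @export
print.ltx_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
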