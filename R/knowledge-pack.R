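#' Rule actions
#'
#' The consequents of a rule are lists of actions. Five kinds exist:
#' `assert_fact` (derive a fact value), `recommend` and `alert` (messages for
#' the clinician, severity `recommend`/`alert`), `set_status` (propose a
#' workflow status), and `request_data` (explicitly ask for fact values).
#'
#' @param fact Fact name to assert.
#' @param value Scalar value to assert.
#' @return An object of class `ltx_action`.
#' @name actions
NULL

#' @rdname actions
#' @export
act_assert <- function(fact, value) {
  stopifnot(is.character(fact), length(fact) == 1L, length(value) == 1L,
            !is.na(value))
  structure(list(kind = "assert_fact", fact = fact, value = value),
            class = "ltx_action")
}

#' @rdname actions
#' @param message Message text.
#' @export
act_recommend <- function(message) {
  structure(list(kind = "recommend", message = message), class = "ltx_action")
}

#' @rdname actions
#' @export
act_alert <- function(message) {
  structure(list(kind = "alert", message = message), class = "ltx_action")
}

#' @rdname actions
#' @param status A legal patient status.
#' @export
act_set_status <- function(status) {
  .check_status(status)
  structure(list(kind = "set_status", status = status), class = "ltx_action")
}

#' @rdname actions
#' @param facts Character vector of fact names to request.
#' @export
act_request <- function(facts) {
  stopifnot(is.character(facts), length(facts) >= 1L)
  structure(list(kind = "request_data", facts = facts), class = "ltx_action")
}

.rule_categories <- c("referral_criteria", "initial_assessment",
                      "waiting_list_placement", "follow_up",
                      "donor_selection", "committee")

#' Create a rule
#'
#' An IF-THEN-ELSE rule: when the antecedent is definitely true the `then`
#' actions apply; when definitely false the `else` actions apply; when unknown
#' the rule is deferred and its unknown facts are recorded as data requests.
#'
#' @param id Unique rule identifier.
#' @param level Decision level (integer >= 1; levels 1-4 in the bundled
#'   referral pack).
#' @param category One of `referral_criteria`, `initial_assessment`,
#'   `waiting_list_placement`, `follow_up`, `donor_selection`, `committee`.
#' @param if_ Antecedent, an `ltx_condition`.
#' @param then List of `ltx_action`s applied when the antecedent is true.
#' @param else_ Optional list of `ltx_action`s applied when definitely false.
#' @param priority Evaluation priority (smaller fires earlier); defaults to
#'   `level`, ties broken by pack order.
#' @return An object of class `ltx_rule`.
#' @export
rule <- function(id, level, category, if_, then, else_ = list(),
                 priority = level) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("rule '", id, "': level must be >= 1")
  category <- match.arg(category, .rule_categories)
  stopifnot(inherits(if_, "ltx_condition"))
  if (inherits(then, "ltx_action")) then <- list(then)
  if (inherits(else_, "ltx_action")) else_ <- list(else_)
  stopifnot(all(vapply(then, inherits, logical(1), "ltx_action")),
            all(vapply(else_, inherits, logical(1), "ltx_action")))
  structure(
    list(id = id, level = level, category = category, if_ = if_,
         then = then, else_ = else_, priority = as.integer(priority)),
    class = "ltx_rule"
  )
}

#' Assemble a knowledge pack
#'
#' A pack bundles a fact dictionary (fact name -> value kind), an ordered rule
#' list, and a conclusions map associating human-readable conclusion tags
#' (e.g. `"referral-criteria-met"`) with the boolean facts that carry them.
#'
#' @param name,version Pack identity strings.
#' @param facts Named character vector: fact name -> kind
#'   (`"number"`/`"boolean"`/`"string"`).
#' @param rules List of [rule()]s.
#' @param conclusions Named character vector: conclusion tag -> fact name.
#' @param metadata Optional list (disease coverage, provenance notes, ...).
#' @return A validated object of class `ltx_pack`.
#' @export
knowledge_pack <- function(name, version = "1.0", facts = character(),
                           rules = list(), conclusions = character(),
                           metadata = list()) {
  pack <- structure(
    list(name = name, version = version, facts = facts, rules = rules,
         conclusions = conclusions, metadata = metadata),
    class = "ltx_pack"
  )
  problems <- .pack_problems(pack)
  if (length(problems)) {
    stop("invalid knowledge pack '", name, "':\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  pack
}

# every invariant violation, not just the first
.pack_problems <- function(pack) {
  problems <- character()
  f <- pack$facts
  if (length(f) && (is.null(names(f)) || any(!nzchar(names(f))))) {
    problems <- c(problems, "fact dictionary entries must be named")
    return(problems)
  }
  bad_kind <- setdiff(unique(unname(f)), c("number", "boolean", "string"))
  if (length(bad_kind)) {
    problems <- c(problems,
                  paste0("unknown fact kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  ids <- vapply(pack$rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    problems <- c(problems, paste0("duplicate rule id(s): ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  declared <- names(f)
  for (r in pack$rules) {
    undecl <- setdiff(condition_facts(r$if_), declared)
    if (length(undecl)) {
      problems <- c(problems, paste0("rule '", r$id,
                                     "' references undeclared fact(s): ",
                                     paste(undecl, collapse = ", ")))
    }
    for (a in c(r$then, r$else_)) {
      if (a$kind == "assert_fact" && !(a$fact %in% declared)) {
        problems <- c(problems, paste0("rule '", r$id,
                                       "' asserts undeclared fact: ", a$fact))
      }
      if (a$kind == "set_status" && !(a$status %in% patient_statuses())) {
        problems <- c(problems, paste0("rule '", r$id,
                                       "' sets illegal status: ", a$status))
      }
    }
  }
  con <- pack$conclusions
  if (length(con)) {
    if (is.null(names(con)) || any(!nzchar(names(con)))) {
      problems <- c(problems, "conclusions must be a named (tag -> fact) vector")
    } else {
      undecl <- setdiff(unname(con), declared)
      if (length(undecl)) {
        problems <- c(problems, paste0("conclusion fact(s) not in dictionary: ",
                                       paste(undecl, collapse = ", ")))
      }
    }
  }
  problems
}

#' @export
print.ltx_pack <- function(x, ...) {
  cat("<knowledge pack '", x$name, "' v", x$version, "> ",
      length(x$rules), " rules, ", length(x$facts), " facts, ",
      length(x$conclusions), " conclusion tags\n", sep = "")
  invisible(x)
}

# ---- serialization: pack <-> plain list (YAML/JSON) ----------------------

.condition_to_list <- function(cond) {
  switch(cond$kind,
    atom = list(fact = cond$fact, op = cond$op,
                value = if (length(cond$value) > 1L) as.list(cond$value)
                        else cond$value),
    and = list(all = lapply(cond$children, .condition_to_list)),
    or  = list(any = lapply(cond$children, .condition_to_list)),
    not = list(not = .condition_to_list(cond$children[[1]]))
  )
}

.condition_from_list <- function(x, where = "condition") {
  if (!is.list(x)) stop("malformed ", where, ": not a mapping")
  if (!is.null(x$all)) {
    return(.cnd_composite("and", lapply(x$all, .condition_from_list, where)))
  }
  if (!is.null(x$any)) {
    return(.cnd_composite("or", lapply(x$any, .condition_from_list, where)))
  }
  if (!is.null(x$not)) return(cnd_not(.condition_from_list(x$not, where)))
  if (!is.null(x$fact)) {
    v <- x$value
    if (is.list(v)) v <- unlist(v)
    if (is.null(v)) stop("malformed ", where, ": atom without value")
    if (is.integer(v)) v <- as.double(v)  # JSON whole numbers
    return(cnd_atom(x$fact, x$op, v))
  }
  stop("malformed ", where, ": expected one of all/any/not/fact, got keys {",
       paste(names(x), collapse = ", "), "}")
}

.action_to_list <- function(a) {
  switch(a$kind,
    assert_fact = list(assert = a$fact, value = a$value),
    recommend = list(recommend = a$message),
    alert = list(alert = a$message),
    set_status = list(set_status = a$status),
    request_data = list(request = as.list(a$facts))
  )
}

.action_from_list <- function(x, where = "action") {
  if (!is.list(x)) stop("malformed ", where)
  if (!is.null(x$assert)) return(act_assert(x$assert, x$value))
  if (!is.null(x$recommend)) return(act_recommend(x$recommend))
  if (!is.null(x$alert)) return(act_alert(x$alert))
  if (!is.null(x$set_status)) return(act_set_status(x$set_status))
  if (!is.null(x$request)) return(act_request(unlist(x$request)))
  stop("malformed ", where, ": expected assert/recommend/alert/set_status/request")
}

#' Serialize a knowledge pack to a plain list / YAML / JSON
#'
#' `pack_to_list()` gives the plain-list form; [write_pack()] writes it as
#' YAML (default) or JSON. `load_pack(write_pack(pack, f))` round-trips.
#'
#' @param pack An `ltx_pack`.
#' @return A plain list mirroring the pack file schema.
#' @export
pack_to_list <- function(pack) {
  stopifnot(inherits(pack, "ltx_pack"))
  list(
    name = pack$name,
    version = pack$version,
    facts = as.list(pack$facts),
    conclusions = as.list(pack$conclusions),
    metadata = pack$metadata,
    rules = lapply(pack$rules, function(r) {
      out <- list(id = r$id, level = r$level, category = r$category,
                  priority = r$priority,
                  `if` = .condition_to_list(r$if_),
                  then = lapply(r$then, .action_to_list))
      if (length(r$else_)) out$else_ <- lapply(r$else_, .action_to_list)
      names(out)[names(out) == "else_"] <- "else"
      out
    })
  )
}

#' @rdname pack_to_list
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return `write_pack()` returns `path` invisibly.
#' @export
write_pack <- function(pack, path) {
  x <- pack_to_list(pack)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Load and validate a knowledge pack
#'
#' Reads a YAML or JSON pack file (top-level keys `name`, `version`, `facts`,
#' `rules`, optionally `conclusions` and `metadata`) and validates every pack
#' invariant, reporting all violations at once.
#'
#' @param path Path to a pack file, or a literal YAML/JSON string.
#' @return A validated `ltx_pack`.
#' @export
load_pack <- function(path) {
  x <- if (is.character(path) && length(path) == 1L && file.exists(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path)
    } else {
      yaml::read_yaml(path)
    }
  } else if (is.character(path)) {
    yaml::yaml.load(paste(path, collapse = "\n"))
  } else {
    stop("load_pack() needs a file path or YAML/JSON text")
  }
  pack_from_list(x)
}

#' @rdname load_pack
#' @param x Plain list as produced by [pack_to_list()].
#' @export
pack_from_list <- function(x) {
  if (is.null(x$name)) stop("pack file missing 'name'")
  facts <- unlist(x$facts)
  if (is.null(facts)) facts <- character()
  conclusions <- unlist(x$conclusions)
  if (is.null(conclusions)) conclusions <- character()
  rules <- lapply(x$rules, function(rx) {
    if (is.null(rx$id)) stop("rule without id")
    rule(
      id = rx$id,
      level = rx$level,
      category = rx$category,
      if_ = .condition_from_list(rx[["if"]], paste0("rule '", rx$id, "' condition")),
      then = lapply(rx$then, .action_from_list),
      else_ = if (is.null(rx[["else"]])) list()
              else lapply(rx[["else"]], .action_from_list),
      priority = if (is.null(rx$priority)) rx$level else rx$priority
    )
  })
  knowledge_pack(
    name = x$name,
    version = if (is.null(x$version)) "1.0" else as.character(x$version),
    facts = facts, rules = rules, conclusions = conclusions,
    metadata = if (is.null(x$metadata)) list() else .deint(x$metadata)
  )
}

# JSON parses whole numbers as integers; normalise to double for stable
# round-trips across YAML and JSON
.deint <- function(x) {
  if (is.integer(x)) as.double(x)
  else if (is.list(x)) lapply(x, .deint)
  else x
}
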