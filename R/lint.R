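#' Lint a knowledge pack
#'
#' Static checks beyond the structural invariants enforced by
#' [knowledge_pack()]:
#'
#' * `self-dependent` — a rule asserting a fact that its own antecedent
#'   requires (it can never enable itself);
#' * `potential contradiction` — two rules asserting the same fact with
#'   different values whose antecedents can hold simultaneously. Overlap is
#'   decided by enumerating candidate values per referenced fact (the operand
#'   values appearing in atoms on that fact, numeric boundary neighbours, an
#'   out-of-vocabulary value, and unknown), which is exact for the pack's
#'   comparator vocabulary; pairs over more than `max_enum_facts` facts are
#'   skipped with a note;
#' * `empty rule` — both `then` and `else` action lists empty.
#'
#' A pure report: the pack is never mutated.
#'
#' @param pack A validated `ltx_pack`.
#' @param max_enum_facts Enumeration cap for the contradiction check.
#' @return An object of class `ltx_lint`: data frame with columns `kind`,
#'   `rule_id`, `detail`.
#' @export
lint_pack <- function(pack, max_enum_facts = 8L) {
  stopifnot(inherits(pack, "ltx_pack"))
  kind <- character(); rule_id <- character(); detail <- character()
  note <- function(k, r, d) {
    kind <<- c(kind, k); rule_id <<- c(rule_id, r); detail <<- c(detail, d)
  }

  for (r in pack$rules) {
    if (length(r$then) == 0L && length(r$else_) == 0L) {
      note("empty rule", r$id, "both then and else action lists are empty")
    }
    needed <- condition_facts(r$if_)
    for (a in c(r$then, r$else_)) {
      if (a$kind == "assert_fact" && a$fact %in% needed) {
        note("self-dependent", r$id,
             paste0("asserts '", a$fact, "' required by its own antecedent"))
      }
    }
  }

  # contradictory assert pairs under overlapping antecedents
  asserts <- list()  # fact -> list of (rule, value, branch)
  for (r in pack$rules) {
    for (branch in c("then", "else")) {
      acts <- if (branch == "then") r$then else r$else_
      for (a in acts) {
        if (a$kind != "assert_fact") next
        asserts[[a$fact]] <- c(asserts[[a$fact]],
                               list(list(rule = r, value = a$value,
                                         branch = branch)))
      }
    }
  }
  for (fact in names(asserts)) {
    entries <- asserts[[fact]]
    if (length(entries) < 2L) next
    for (i in seq_len(length(entries) - 1L)) {
      for (j in seq(i + 1L, length(entries))) {
        e1 <- entries[[i]]; e2 <- entries[[j]]
        if (e1$rule$id == e2$rule$id) next  # then/else of one rule never co-fire
        if (.scalar_eq(e1$value, e2$value)) next
        ov <- .branches_overlap(e1$rule$if_, e1$branch,
                                e2$rule$if_, e2$branch, max_enum_facts)
        if (is.na(ov)) {
          note("enumeration skipped", e1$rule$id,
               paste0("contradiction check vs '", e2$rule$id, "' on '", fact,
                      "' skipped: more than ", max_enum_facts,
                      " facts to enumerate"))
        } else if (ov) {
          note("potential contradiction", e1$rule$id,
               paste0("and '", e2$rule$id, "' assert '", fact,
                      "' with different values under overlapping antecedents"))
        }
      }
    }
  }

  structure(
    list(findings = data.frame(kind = kind, rule_id = rule_id, detail = detail,
                               stringsAsFactors = FALSE),
         n_rules = length(pack$rules)),
    class = "ltx_lint"
  )
}

# candidate fact values for exact-ish enumeration: every operand mentioned in
# atoms on the fact, numeric neighbours of thresholds, one fresh string, and
# unknown (NA)
.candidate_values <- function(atoms) {
  vals <- list(NA)
  for (a in atoms) {
    for (v in a$value) {
      vals <- c(vals, list(v))
      if (is.numeric(v)) vals <- c(vals, list(v - 1, v + 1))
    }
    if (is.character(a$value[1])) vals <- c(vals, list("other"))
    if (is.logical(a$value[1])) vals <- c(vals, list(TRUE, FALSE))
  }
  unique(vals)
}

# TRUE if some joint fact assignment makes both branch conditions hold
# (then-branch: antecedent TRUE; else-branch: antecedent FALSE); NA if the
# enumeration cap is exceeded
.branches_overlap <- function(c1, b1, c2, b2, max_enum_facts) {
  facts <- union(condition_facts(c1), condition_facts(c2))
  if (length(facts) > max_enum_facts) return(NA)
  atoms <- c(condition_atoms(c1), condition_atoms(c2))
  domains <- lapply(facts, function(f) {
    .candidate_values(Filter(function(a) a$fact == f, atoms))
  })
  names(domains) <- facts
  idx <- rep(1L, length(facts))
  sizes <- vapply(domains, length, integer(1))
  want1 <- b1 == "then"; want2 <- b2 == "then"
  repeat {
    assign <- stats::setNames(
      lapply(seq_along(facts), function(k) domains[[k]][[idx[k]]]), facts)
    v1 <- eval_condition(c1, assign)
    v2 <- eval_condition(c2, assign)
    if (identical(isTRUE(v1), want1) && identical(isTRUE(v1) || isFALSE(v1), TRUE) &&
        identical(isTRUE(v2), want2) && identical(isTRUE(v2) || isFALSE(v2), TRUE)) {
      return(TRUE)
    }
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
      if (k > length(facts)) return(FALSE)
    }
  }
}

#' @export
print.ltx_lint <- function(x, ...) {
  cat("<lint report> ", nrow(x$findings), " finding(s) over ", x$n_rules,
      " rules\n", sep = "")
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      cat("  [", x$findings$kind[i], "] ", x$findings$rule_id[i], ": ",
          x$findings$detail[i], "\n", sep = "")
    }
  }
  invisible(x)
}
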