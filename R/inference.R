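#' Forward-chaining inference
#'
#' Evaluates a knowledge pack against a fact map until fixpoint. In each pass
#' the not-yet-settled rules are evaluated in priority order (smaller priority
#' first, ties by pack order): a rule whose antecedent is definitely true
#' *fires* (its `then` actions apply), one whose antecedent is definitely
#' false settles through its `else` actions, and one whose antecedent is
#' unknown is deferred, its unknown atoms recorded as data requests. Inference
#' stops when a full pass settles nothing. Each rule fires at most once, so
#' termination is guaranteed; derived facts are monotone (a conflicting
#' re-assertion is a hard error, never a silent overwrite).
#'
#' @param facts Named list of input facts (absent or `NA` = unknown), or an
#'   [patient_record()] (its [record_facts()] are used).
#' @param pack A validated `ltx_pack`.
#' @return An object of class `ltx_inference` with elements:
#'   \describe{
#'     \item{derived}{named list of facts derived by rules (inputs excluded)}
#'     \item{facts}{the full final fact map (inputs + derived)}
#'     \item{fired}{data frame of then-fired rules: `rule_id`, `pass`,
#'       with the bound antecedent snapshot in `$snapshots`}
#'     \item{settled_false}{rule ids whose antecedent was definitely false
#'       (else actions applied)}
#'     \item{messages}{data frame `severity` (`info`/`recommend`/`alert`),
#'       `message`, `rule_id`}
#'     \item{data_requests}{fact names whose unknown-ness blocked >= 1 rule}
#'     \item{conclusions}{conclusion tags whose fact ended definitely true}
#'     \item{status_proposals}{statuses proposed by `set_status` actions}
#'   }
#' @examples
#' pack <- builtin_referral_pack()
#' res <- infer(list(age = 50, ESLD = TRUE, survival_lt_50pct = TRUE,
#'                   advanced_despite_treatment = TRUE,
#'                   diagnosis_confirmed = TRUE, disease_permitted = TRUE,
#'                   FEV1_flag = TRUE, dyspnea_history = TRUE,
#'                   recurrent_hospitalization = TRUE,
#'                   nyha_symptoms = "daily-activity-only"), pack)
#' res$conclusions
#' @export
infer <- function(facts, pack) {
  stopifnot(inherits(pack, "ltx_pack"))
  if (inherits(facts, "ltx_patient")) facts <- record_facts(facts)
  stopifnot(is.list(facts))
  # drop NA inputs: NA and absent both mean unknown
  known <- facts[!vapply(facts, function(v) length(v) == 1L && is.na(v), logical(1))]
  input_names <- names(known)

  n <- length(pack$rules)
  ord <- order(vapply(pack$rules, `[[`, integer(1), "priority"), seq_len(n))
  rules <- pack$rules[ord]

  state <- known
  settled <- rep(FALSE, n)       # fired (then) or else-applied
  fired_ids <- character()
  fired_pass <- integer()
  snapshots <- list()
  settled_false_ids <- character()
  msgs_sev <- character(); msgs_txt <- character(); msgs_rule <- character()
  requests <- character()
  status_proposals <- character()
  asserted_by <- list()          # fact -> rule id that derived it

  apply_actions <- function(actions, r, state) {
    for (a in actions) {
      if (a$kind == "assert_fact") {
        cur <- state[[a$fact]]
        if (!is.null(cur)) {
          if (!.scalar_eq(cur, a$value)) {
            other <- asserted_by[[a$fact]]
            stop("inference conflict on fact '", a$fact, "': rule '", r$id,
                 "' asserts ", format(a$value), " but ",
                 if (is.null(other)) "the input facts hold "
                 else paste0("rule '", other, "' derived "),
                 format(cur), call. = FALSE)
          }
        } else {
          state[[a$fact]] <- a$value
          asserted_by[[a$fact]] <<- r$id
        }
      } else if (a$kind == "recommend" || a$kind == "alert") {
        msgs_sev <<- c(msgs_sev, if (a$kind == "alert") "alert" else "recommend")
        msgs_txt <<- c(msgs_txt, a$message)
        msgs_rule <<- c(msgs_rule, r$id)
      } else if (a$kind == "set_status") {
        status_proposals <<- c(status_proposals, a$status)
      } else if (a$kind == "request_data") {
        requests <<- c(requests, a$facts)
      }
    }
    state
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    progressed <- FALSE
    requests_this_pass <- character()
    for (i in seq_len(n)) {
      if (settled[i]) next
      r <- rules[[i]]
      v <- eval_condition(r$if_, state)
      if (isTRUE(v)) {
        snap <- state[intersect(condition_facts(r$if_), names(state))]
        state <- apply_actions(r$then, r, state)
        settled[i] <- TRUE
        progressed <- TRUE
        fired_ids <- c(fired_ids, r$id)
        fired_pass <- c(fired_pass, pass)
        snapshots[[r$id]] <- snap
      } else if (isFALSE(v)) {
        state <- apply_actions(r$else_, r, state)
        settled[i] <- TRUE
        progressed <- TRUE
        settled_false_ids <- c(settled_false_ids, r$id)
      } else {
        requests_this_pass <- c(requests_this_pass, .blocking_facts(r$if_, state))
      }
    }
    if (!progressed) {
      requests <- c(requests, requests_this_pass)
      break
    }
    if (pass > n + 1L) stop("internal error: pass count exceeded rule count")
  }

  derived <- state[setdiff(names(state), input_names)]
  con <- pack$conclusions
  concluded <- if (length(con)) {
    names(con)[vapply(unname(con), function(f) isTRUE(state[[f]]), logical(1))]
  } else character()

  structure(
    list(derived = derived, facts = state,
         fired = data.frame(rule_id = fired_ids, pass = fired_pass,
                            stringsAsFactors = FALSE),
         snapshots = snapshots,
         settled_false = settled_false_ids,
         messages = data.frame(severity = msgs_sev, message = msgs_txt,
                               rule_id = msgs_rule, stringsAsFactors = FALSE),
         data_requests = unique(requests),
         conclusions = concluded,
         status_proposals = unique(status_proposals),
         asserted_by = asserted_by,
         conclusion_facts = con,
         input_facts = known,
         pack_name = pack$name, pack_version = pack$version),
    class = "ltx_inference"
  )
}

#' @export
print.ltx_inference <- function(x, ...) {
  cat("<inference over pack '", x$pack_name, "'>\n", sep = "")
  cat("  fired rules (", nrow(x$fired), "): ",
      paste(x$fired$rule_id, collapse = ", "), "\n", sep = "")
  if (length(x$conclusions)) {
    cat("  conclusions: ", paste(x$conclusions, collapse = ", "), "\n", sep = "")
  }
  if (length(x$derived)) {
    cat("  derived: ",
        paste(names(x$derived), vapply(x$derived, format, character(1)),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$messages)) {
    for (i in seq_len(nrow(x$messages))) {
      cat("  [", x$messages$severity[i], "] ", x$messages$message[i],
          " (", x$messages$rule_id[i], ")\n", sep = "")
    }
  }
  if (length(x$data_requests)) {
    cat("  data requested: ", paste(x$data_requests, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Explain a conclusion
#'
#' Builds the explanation tree for a conclusion tag of an inference result:
#' the root is the rule that derived the conclusion fact, its children are the
#' antecedent atoms, and each atom either rests on an input fact (a leaf) or
#' expands recursively into the rule that derived its fact.
#'
#' @param result An `ltx_inference`.
#' @param conclusion A conclusion tag present in `result$conclusions`, or a
#'   derived fact name.
#' @return A tree of class `ltx_explanation`; nodes have `type`
#'   (`"rule"`/`"fact"`), `label`, and `children`.
#' @export
explain <- function(result, conclusion) {
  stopifnot(inherits(result, "ltx_inference"),
            is.character(conclusion), length(conclusion) == 1L)
  con_map <- result$conclusion_facts
  fact <- if (conclusion %in% names(con_map)) {
    if (!(conclusion %in% result$conclusions)) {
      stop("conclusion '", conclusion, "' was not reached in this inference")
    }
    unname(con_map[[conclusion]])
  } else {
    conclusion
  }
  if (!(fact %in% names(result$facts))) {
    stop("unknown conclusion or fact: '", conclusion, "'")
  }
  .explain_fact(result, fact, depth = 0L)
}

.explain_fact <- function(result, fact, depth) {
  if (depth > 50L) stop("explanation depth exceeded")
  by <- result$asserted_by[[fact]]
  if (is.null(by)) {
    # input fact: leaf
    v <- result$facts[[fact]]
    return(structure(list(type = "fact", label = fact,
                          value = v, children = list()),
                     class = "ltx_explanation"))
  }
  # find the rule in the trace and expand its antecedent atoms
  snap <- result$snapshots[[by]]
  kids <- lapply(names(snap), function(f) .explain_fact(result, f, depth + 1L))
  structure(
    list(type = "rule", label = by, fact = fact,
         value = result$facts[[fact]], children = kids),
    class = "ltx_explanation"
  )
}

#' @export
print.ltx_explanation <- function(x, ..., indent = 0) {
  pad <- strrep("  ", indent)
  if (x$type == "rule") {
    cat(pad, "[rule ", x$label, "] => ", x$fact, " = ", format(x$value),
        "\n", sep = "")
  } else {
    cat(pad, x$label, " = ", format(x$value), " (input)\n", sep = "")
  }
  for (ch in x$children) print(ch, indent = indent + 1)
  invisible(x)
}
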