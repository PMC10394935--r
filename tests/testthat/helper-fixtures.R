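# shared fixtures and independent oracles used across test files

# the fully satisfied COPD referral worked example
copd_facts <- function() {
  list(age = 50, ESLD = TRUE, survival_lt_50pct = TRUE,
       advanced_despite_treatment = TRUE, diagnosis_confirmed = TRUE,
       disease_permitted = TRUE, FEV1_flag = TRUE, dyspnea_history = TRUE,
       recurrent_hospitalization = TRUE, nyha_symptoms = "daily-activity-only")
}

# ---- independent Kleene-logic oracle -------------------------------------
# evaluates a condition tree given a fact assignment, with explicit truth
# tables and its own atom evaluator; shares no code with eval_condition()

oracle_atom <- function(a, facts) {
  v <- facts[[a$fact]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA)
  switch(a$op,
    eq = if (identical(v, a$value)) TRUE else FALSE,
    ne = if (identical(v, a$value)) FALSE else TRUE,
    lt = v < a$value, le = v <= a$value,
    gt = v > a$value, ge = v >= a$value,
    in_set = any(vapply(a$value, identical, logical(1), x = v)))
}

oracle_eval <- function(cond, facts) {
  if (cond$kind == "atom") return(oracle_atom(cond, facts))
  if (cond$kind == "not") {
    v <- oracle_eval(cond$children[[1]], facts)
    return(if (is.na(v)) NA else !v)
  }
  vals <- vapply(cond$children, oracle_eval, logical(1), facts = facts)
  if (cond$kind == "and") {
    if (any(vals %in% FALSE)) FALSE else if (anyNA(vals)) NA else TRUE
  } else {  # or
    if (any(vals %in% TRUE)) TRUE else if (anyNA(vals)) NA else FALSE
  }
}

# random condition tree over boolean facts f1..fk (atoms test "eq TRUE")
random_condition <- function(k, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    return(cnd_atom(paste0("f", sample.int(k, 1)), "eq", TRUE))
  }
  kind <- sample(c("and", "or", "not"), 1)
  if (kind == "not") return(cnd_not(random_condition(k, depth - 1)))
  n_ch <- sample(2:3, 1)
  kids <- lapply(seq_len(n_ch), function(i) random_condition(k, depth - 1))
  if (kind == "and") cnd_all(kids) else cnd_any(kids)
}

# all {TRUE, FALSE, NA}^k assignments over facts f1..fk as fact maps
# (memoised: the same grids are reused across hundreds of random conditions)
.tfu_cache <- new.env(parent = emptyenv())
tfu_assignments <- function(k) {
  key <- as.character(k)
  if (!is.null(.tfu_cache[[key]])) return(.tfu_cache[[key]])
  grid <- expand.grid(rep(list(c(TRUE, FALSE, NA)), k))
  names(grid) <- paste0("f", seq_len(k))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, , drop = FALSE])
    row[!vapply(row, is.na, logical(1))]  # unknown = absent
  })
  .tfu_cache[[key]] <- out
  out
}

# ---- independent forward-chaining closure oracle -------------------------
# repeated full scanning over all rules until no change; no firing bookkeeping

oracle_closure <- function(pack, facts) {
  state <- facts
  repeat {
    changed <- FALSE
    for (r in pack$rules) {
      v <- oracle_eval(r$if_, state)
      acts <- if (isTRUE(v)) r$then else if (isFALSE(v)) r$else_ else list()
      for (a in acts) {
        if (a$kind == "assert_fact" && is.null(state[[a$fact]])) {
          state[[a$fact]] <- a$value
          changed <- TRUE
        }
      }
    }
    if (!changed) return(state)
  }
}

# random conflict-free pack: rule i asserts its own derived fact d_i
# (TRUE on then, FALSE on else) from antecedents over inputs and other
# derived facts
random_pack <- function(n_inputs, n_rules, p_else = 0.7) {
  input_facts <- paste0("f", seq_len(n_inputs))
  derived <- paste0("d", seq_len(n_rules))
  all_facts <- stats::setNames(rep("boolean", n_inputs + n_rules),
                               c(input_facts, derived))
  rules <- lapply(seq_len(n_rules), function(i) {
    pool <- c(input_facts, derived[seq_len(n_rules) != i])
    n_at <- sample(1:3, 1)
    atoms <- lapply(sample(pool, n_at), function(f)
      cnd_atom(f, "eq", sample(c(TRUE, FALSE), 1)))
    cond <- if (n_at == 1) atoms[[1]]
            else if (stats::runif(1) < 0.5) cnd_all(atoms) else cnd_any(atoms)
    if (stats::runif(1) < 0.3) cond <- cnd_not(cond)
    rule(paste0("r", i), level = sample(1:4, 1),
         category = "referral_criteria", if_ = cond,
         then = act_assert(derived[i], TRUE),
         else_ = if (stats::runif(1) < p_else)
           act_assert(derived[i], FALSE) else list())
  })
  knowledge_pack("random", facts = all_facts, rules = rules)
}

random_bool_facts <- function(n_inputs, p_unknown = 0.3) {
  vals <- sample(c(TRUE, FALSE, NA), n_inputs, replace = TRUE,
                 prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown))
  out <- stats::setNames(as.list(vals), paste0("f", seq_len(n_inputs)))
  out[!vapply(out, is.na, logical(1))]
}

# Table 7 per-respondent PSSUQ subscale scores as printed
pssuq_table7 <- function() {
  data.frame(
    system_usefulness   = c(7, 5.83, 5.33, 6.67, 5.5, 6.67),
    information_quality = c(7, 6, 5.5, 7, 5.33, 7),
    interface_quality   = c(7, 6, 5.25, 6.5, 5.5, 7),
    overall             = c(7, 6, 4.83, 6.5, 6.25, 6.67)
  )
}
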