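test_that("empty fact map fires nothing and requests the missing data", {
  res <- infer(list(), builtin_referral_pack())
  expect_identical(nrow(res$fired), 0L)
  expect_gt(length(res$data_requests), 0)
  expect_true(all(c("age", "ESLD") %in% res$data_requests))
  expect_length(res$conclusions, 0)
})

test_that("the COPD worked example chains through all four levels", {
  res <- infer(copd_facts(), builtin_referral_pack())
  expect_identical(res$facts$nyha_class, "III")
  expect_true("referral-criteria-met" %in% res$conclusions)
  expect_true("general-criteria-met" %in% res$conclusions)
  expect_match(res$messages$message[res$messages$severity == "recommend"],
               "criteria of referral", all = FALSE)
  # derived facts chain: symptoms -> class III -> advanced-NYHA -> referral
  expect_true(res$facts$nyha_advanced)
  expect_true(res$facts$referral_criteria_met)
})

test_that("flipping one criterion to false takes the else path", {
  facts <- copd_facts()
  facts$recurrent_hospitalization <- FALSE
  res <- infer(facts, builtin_referral_pack())
  expect_false("referral-criteria-met" %in% res$conclusions)
  expect_false(res$facts$referral_criteria_met)
  expect_true("copd_referral" %in% res$settled_false)
  expect_true(any(res$messages$severity == "alert"))
})

test_that("conflicting assertions are a loud error naming both sources", {
  pack <- knowledge_pack("conflict", facts = c(a = "boolean", c = "boolean"),
    rules = list(
      rule("r_pos", 1, "referral_criteria", cnd_atom("a", "eq", TRUE),
           then = act_assert("c", TRUE)),
      rule("r_neg", 2, "referral_criteria", cnd_atom("a", "eq", TRUE),
           then = act_assert("c", FALSE))))
  err <- tryCatch(infer(list(a = TRUE), pack), error = conditionMessage)
  expect_match(err, "inference conflict")
  expect_match(err, "r_pos")
  expect_match(err, "r_neg")
  # input facts are never silently overwritten either
  err2 <- tryCatch(infer(list(a = TRUE, c = FALSE), pack),
                   error = conditionMessage)
  expect_match(err2, "inference conflict")
  # re-asserting the same value is not a conflict
  pack2 <- knowledge_pack("agree", facts = c(a = "boolean", c = "boolean"),
    rules = list(
      rule("r1", 1, "referral_criteria", cnd_atom("a", "eq", TRUE),
           then = act_assert("c", TRUE)),
      rule("r2", 2, "referral_criteria", cnd_atom("a", "eq", TRUE),
           then = act_assert("c", TRUE))))
  expect_silent(infer(list(a = TRUE), pack2))
})

test_that("each rule fires at most once and passes are bounded", {
  set.seed(11)
  for (i in 1:50) {
    pack <- random_pack(n_inputs = 5, n_rules = sample(3:12, 1))
    res <- infer(random_bool_facts(5), pack)
    expect_lte(nrow(res$fired), length(pack$rules))
    expect_false(anyDuplicated(res$fired$rule_id) > 0)
    expect_lte(max(c(0L, res$fired$pass)), length(pack$rules) + 1L)
  }
})

test_that("engine conclusions equal brute-force closure on random packs", {
  set.seed(99)
  n_pairs <- 1000
  for (i in seq_len(n_pairs)) {
    n_in <- sample(3:10, 1)
    pack <- random_pack(n_inputs = n_in, n_rules = sample(3:15, 1))
    facts <- random_bool_facts(n_in)
    engine <- infer(facts, pack)$facts
    oracle <- oracle_closure(pack, facts)
    expect_identical(engine[order(names(engine))],
                     oracle[order(names(oracle))],
                     info = paste("pair", i))
  }
})

test_that("derived facts grow monotonically across passes", {
  # chain d1 <- f1; d2 <- d1; d3 <- d2 forces multiple passes
  pack <- knowledge_pack("chain",
    facts = c(f1 = "boolean", d1 = "boolean", d2 = "boolean", d3 = "boolean"),
    rules = list(
      rule("r3", 1, "referral_criteria", cnd_atom("d2", "eq", TRUE),
           then = act_assert("d3", TRUE)),
      rule("r2", 1, "referral_criteria", cnd_atom("d1", "eq", TRUE),
           then = act_assert("d2", TRUE)),
      rule("r1", 1, "referral_criteria", cnd_atom("f1", "eq", TRUE),
           then = act_assert("d1", TRUE))))
  res <- infer(list(f1 = TRUE), pack)
  expect_setequal(names(res$derived), c("d1", "d2", "d3"))
  expect_true(all(unlist(res$derived)))
})

test_that("permuting rules with distinct priorities leaves facts unchanged", {
  set.seed(7)
  for (i in 1:20) {
    pack <- random_pack(n_inputs = 6, n_rules = 8)
    # distinct priorities
    for (j in seq_along(pack$rules)) pack$rules[[j]]$priority <- j
    facts <- random_bool_facts(6)
    base <- infer(facts, pack)$facts
    perm <- pack
    perm$rules <- perm$rules[sample(seq_along(perm$rules))]
    permuted <- infer(facts, perm)$facts
    expect_identical(base[order(names(base))], permuted[order(names(permuted))])
  }
})

test_that("adding an irrelevant unknown fact never changes conclusions", {
  pack <- builtin_referral_pack()
  f1 <- copd_facts()
  f2 <- c(f1, list(totally_unrelated = NA))
  expect_identical(infer(f1, pack)$conclusions, infer(f2, pack)$conclusions)
})

test_that("explain builds the four-branch COPD tree down to input facts", {
  res <- infer(copd_facts(), builtin_referral_pack())
  tree <- explain(res, "referral-criteria-met")
  expect_identical(tree$type, "rule")
  expect_identical(tree$label, "copd_referral")
  expect_length(tree$children, 4)
  labels <- vapply(tree$children, `[[`, character(1), "label")
  # NYHA branch expands into the class-III rule; the rest are input leaves
  nyha <- tree$children[[which(labels == "nyha_advanced")]]
  expect_identical(nyha$type, "rule")
  leaf_types <- vapply(tree$children[labels != "nyha_advanced"],
                       `[[`, character(1), "type")
  expect_true(all(leaf_types == "fact"))
  # every leaf of the full tree is an input fact
  leaves <- function(nd) {
    if (length(nd$children) == 0) list(nd)
    else unlist(lapply(nd$children, leaves), recursive = FALSE)
  }
  for (lf in leaves(tree)) expect_identical(lf$type, "fact")
})

test_that("explaining a depth-one conclusion and unknown tags behave", {
  pack <- knowledge_pack("one", facts = c(a = "boolean", c = "boolean"),
    conclusions = c(done = "c"),
    rules = list(rule("r1", 1, "referral_criteria",
                      cnd_atom("a", "eq", TRUE), then = act_assert("c", TRUE))))
  res <- infer(list(a = TRUE), pack)
  tree <- explain(res, "done")
  expect_identical(tree$label, "r1")
  expect_length(tree$children, 1)
  expect_identical(tree$children[[1]]$type, "fact")
  expect_error(explain(res, "nonexistent"), "unknown conclusion")
})

test_that("explicit request_data actions surface as data requests", {
  pack <- knowledge_pack("req", facts = c(a = "boolean"),
    rules = list(rule("r1", 1, "referral_criteria",
                      cnd_atom("a", "eq", TRUE),
                      then = act_request(c("lab_x", "lab_y")))))
  res <- infer(list(a = TRUE), pack)
  expect_true(all(c("lab_x", "lab_y") %in% res$data_requests))
})
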