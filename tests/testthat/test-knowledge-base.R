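test_that("three-valued evaluation follows Kleene truth tables", {
  a <- cnd_atom("u", "eq", TRUE)   # unknown below
  t_ <- cnd_atom("t", "eq", TRUE)
  f_ <- cnd_atom("f", "eq", TRUE)
  facts <- list(t = TRUE, f = FALSE)
  expect_true(is.na(eval_condition(a, facts)))                 # unknown atom
  expect_true(is.na(eval_condition(cnd_all(a, t_), facts)))    # U AND T = U
  expect_false(eval_condition(cnd_all(a, f_), facts))          # U AND F = F
  expect_true(eval_condition(cnd_any(a, t_), facts))           # U OR T = T
  expect_true(is.na(eval_condition(cnd_any(a, f_), facts)))    # U OR F = U
  expect_true(is.na(eval_condition(cnd_not(a), facts)))        # NOT U = U
})

test_that("comparators handle numbers, strings, sets and type mismatches", {
  f <- list(x = 5, s = "COPD", b = TRUE)
  expect_true(eval_condition(cnd_atom("x", "ge", 5), f))
  expect_false(eval_condition(cnd_atom("x", "gt", 5), f))
  expect_true(eval_condition(cnd_atom("s", "in_set", c("COPD", "IPF")), f))
  expect_false(eval_condition(cnd_atom("s", "ne", "COPD"), f))
  expect_false(eval_condition(cnd_atom("b", "eq", FALSE), f))
  # non-numeric value under a numeric comparator is unknown, not an error
  expect_true(is.na(eval_condition(cnd_atom("s", "lt", 3), f)))
  # cross-kind equality is definite false
  expect_false(eval_condition(cnd_atom("x", "eq", "5"), f))
})

test_that("condition evaluation matches brute-force enumeration (sample)", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(1:4, 1)
    cond <- random_condition(k)
    for (facts in tfu_assignments(k)) {
      expect_identical(eval_condition(cond, facts), oracle_eval(cond, facts),
                       info = paste("cond:", format(cond)))
    }
  }
})

test_that("the bundled referral pack loads with at least 13 rules", {
  pack <- builtin_referral_pack()
  expect_gte(length(pack$rules), 13)
  shipped <- load_pack(system.file("extdata", "imamltx-referral.yaml",
                                   package = "ltxcdss"))
  expect_identical(pack_to_list(shipped), pack_to_list(pack))
})

test_that("pack validation lists every violation, not only the first", {
  bad <- 'name: bad
version: "1"
facts: {a: boolean}
rules:
  - id: r1
    level: 1
    category: referral_criteria
    if: {fact: xyz, op: eq, value: true}
    then: [{assert: a, value: true}]
  - id: r1
    level: 1
    category: referral_criteria
    if: {fact: qqq, op: eq, value: true}
    then: [{assert: a, value: true}]'
  err <- tryCatch(load_pack(bad), error = conditionMessage)
  expect_match(err, "xyz")
  expect_match(err, "qqq")
  expect_match(err, "duplicate rule id")
})

test_that("an empty rule list is a valid pack", {
  p <- knowledge_pack("empty", facts = c(a = "boolean"), rules = list())
  expect_s3_class(p, "ltx_pack")
  expect_length(p$rules, 0)
})

test_that("age rule encodes the corrected 14-65 band", {
  pack <- builtin_referral_pack()
  expect_true(infer(list(age = 40), pack)$facts$age_criterion)
  expect_false(infer(list(age = 70), pack)$facts$age_criterion)
  expect_false(infer(list(age = 10), pack)$facts$age_criterion)
  expect_true(infer(list(age = 14), pack)$facts$age_criterion)
  expect_true(infer(list(age = 65), pack)$facts$age_criterion)
  # the band is configurable
  wide <- builtin_referral_pack(age_min = 10, age_max = 70)
  expect_true(infer(list(age = 70), wide)$facts$age_criterion)
})

test_that("COPD conjunction concludes referral when all four criteria hold", {
  pack <- builtin_referral_pack()
  res <- infer(list(FEV1_flag = TRUE, dyspnea_history = TRUE,
                    recurrent_hospitalization = TRUE, nyha_class = "III"),
               pack)
  expect_true("referral-criteria-met" %in% res$conclusions)
  expect_true(res$facts$referral_criteria_met)
})

test_that("FEV1 rule derives the flag from fev1_pct per pack parameters", {
  pack <- builtin_referral_pack()
  expect_true(infer(list(fev1_pct = 50), pack)$facts$FEV1_flag)   # > 35 as printed
  expect_false(infer(list(fev1_pct = 30), pack)$facts$FEV1_flag)
  flipped <- builtin_referral_pack(fev1_comparator = "lt")
  expect_true(infer(list(fev1_pct = 30), flipped)$facts$FEV1_flag)
})

test_that("the four NYHA rules never assign two classes to one fact-state", {
  pack <- builtin_referral_pack()
  nyha_rules <- Filter(function(r) startsWith(r$id, "nyha_class_"), pack$rules)
  expect_length(nyha_rules, 4)
  for (sym in c("none", "normal-activity", "daily-activity-only", "at-rest",
                "other", NA)) {
    facts <- if (is.na(sym)) list() else list(nyha_symptoms = sym)
    firing <- Filter(function(r) isTRUE(eval_condition(r$if_, facts)),
                     nyha_rules)
    expect_lte(length(firing), 1)
  }
})

test_that("serialization round-trips through YAML and JSON", {
  pack <- builtin_referral_pack()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_pack(pack, f)
    expect_identical(pack_to_list(load_pack(f)), pack_to_list(pack))
  }
})

test_that("lint flags self-dependent rules", {
  p <- knowledge_pack("selfdep", facts = c(a = "boolean"),
    rules = list(rule("r1", 1, "referral_criteria",
                      cnd_atom("a", "eq", TRUE),
                      then = act_assert("a", TRUE))))
  lint <- lint_pack(p)
  expect_true("self-dependent" %in% lint$findings$kind)
})

test_that("lint flags contradictory asserts under overlapping antecedents", {
  # r1: x >= 10 -> c=TRUE ; r2: x <= 20 -> c=FALSE ; overlap on 10..20
  p <- knowledge_pack("contra", facts = c(x = "number", c = "boolean"),
    rules = list(
      rule("r1", 1, "referral_criteria", cnd_atom("x", "ge", 10),
           then = act_assert("c", TRUE)),
      rule("r2", 1, "referral_criteria", cnd_atom("x", "le", 20),
           then = act_assert("c", FALSE))))
  lint <- lint_pack(p)
  expect_true("potential contradiction" %in% lint$findings$kind)
  # disjoint antecedents are not flagged
  q <- knowledge_pack("clean", facts = c(x = "number", c = "boolean"),
    rules = list(
      rule("r1", 1, "referral_criteria", cnd_atom("x", "ge", 10),
           then = act_assert("c", TRUE)),
      rule("r2", 1, "referral_criteria", cnd_atom("x", "lt", 10),
           then = act_assert("c", FALSE))))
  expect_false("potential contradiction" %in% lint_pack(q)$findings$kind)
})

test_that("the bundled pack lints clean", {
  lint <- lint_pack(builtin_referral_pack())
  expect_identical(nrow(lint$findings), 0L)
})
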