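#' Bundled lung-transplant referral knowledge pack
#'
#' Encodes the published referral-investigation rules across four decision
#' levels:
#'
#' * Level 1 — general criteria: an age band (see below) and the end-stage
#'   lung disease triplet (`ESLD`, estimated survival below 50%
#'   (`survival_lt_50pct`), disease advanced despite optimal treatment
#'   (`advanced_despite_treatment`)).
#' * Level 2 — NYHA functional class assignment from the symptom description
#'   (`nyha_symptoms`: `"none"`, `"normal-activity"`, `"daily-activity-only"`,
#'   `"at-rest"` map to classes I-IV); the four rules are mutually exclusive.
#' * Level 3 — diagnosis confirmation (`diagnosis_confirmed`) and the
#'   centre's permitted-disease check (`disease_permitted`).
#' * Level 4 — COPD-specific referral: `FEV1_flag AND dyspnea_history AND
#'   recurrent_hospitalization AND nyha_class in {III, IV}` concludes
#'   *referral-criteria-met*. `FEV1_flag` may be supplied directly or derived
#'   from `fev1_pct` by the comparator/threshold parameters.
#'
#' The source material prints the age rule as an unsatisfiable band
#' (`age >= 65 and age >= 14`); it is encoded here as
#' `age_min <= age <= age_max`, both configurable. The printed FEV1 rule
#' (`FEV1 > 35%`) is encoded exactly as printed, but comparator and threshold
#' are parameters because the printed direction is at odds with usual COPD
#' referral practice — the engine is agnostic, the pack is data.
#'
#' @param age_min,age_max Age eligibility band in years.
#' @param fev1_threshold FEV1 threshold, percent of predicted.
#' @param fev1_comparator Comparator for the FEV1 rule (default `"gt"`, as
#'   printed).
#' @return A validated `ltx_pack` with 13 rules.
#' @examples
#' pack <- builtin_referral_pack()
#' infer(list(age = 40), pack)$derived$age_criterion
#' @export
builtin_referral_pack <- function(age_min = 14, age_max = 65,
                                  fev1_threshold = 35,
                                  fev1_comparator = c("gt", "ge", "lt", "le")) {
  fev1_comparator <- match.arg(fev1_comparator)
  facts <- c(
    age = "number",
    age_criterion = "boolean",
    ESLD = "boolean",
    survival_lt_50pct = "boolean",
    advanced_despite_treatment = "boolean",
    esld_criterion = "boolean",
    general_criteria_met = "boolean",
    nyha_symptoms = "string",
    nyha_class = "string",
    diagnosis_confirmed = "boolean",
    disease_permitted = "boolean",
    dx_criterion = "boolean",
    disease_criterion = "boolean",
    diagnosis_criteria_met = "boolean",
    fev1_pct = "number",
    FEV1_flag = "boolean",
    dyspnea_history = "boolean",
    recurrent_hospitalization = "boolean",
    nyha_advanced = "boolean",
    referral_criteria_met = "boolean"
  )
  rules <- list(
    # level 1: general criteria
    rule("age_band", 1L, "referral_criteria",
         cnd_all(cnd_atom("age", "ge", age_min), cnd_atom("age", "le", age_max)),
         then = act_assert("age_criterion", TRUE),
         else_ = list(act_assert("age_criterion", FALSE),
                      act_alert("patient is outside the age eligibility band"))),
    rule("esld_triplet", 1L, "referral_criteria",
         cnd_all(cnd_atom("ESLD", "eq", TRUE),
                 cnd_atom("survival_lt_50pct", "eq", TRUE),
                 cnd_atom("advanced_despite_treatment", "eq", TRUE)),
         then = act_assert("esld_criterion", TRUE),
         else_ = act_assert("esld_criterion", FALSE)),
    rule("general_criteria", 1L, "referral_criteria",
         cnd_all(cnd_atom("age_criterion", "eq", TRUE),
                 cnd_atom("esld_criterion", "eq", TRUE)),
         then = act_assert("general_criteria_met", TRUE),
         else_ = list(act_assert("general_criteria_met", FALSE),
                      act_alert("general referral criteria not met"))),
    # level 2: NYHA class from symptom description (mutually exclusive)
    rule("nyha_class_I", 2L, "referral_criteria",
         cnd_atom("nyha_symptoms", "eq", "none"),
         then = act_assert("nyha_class", "I")),
    rule("nyha_class_II", 2L, "referral_criteria",
         cnd_atom("nyha_symptoms", "eq", "normal-activity"),
         then = act_assert("nyha_class", "II")),
    rule("nyha_class_III", 2L, "referral_criteria",
         cnd_atom("nyha_symptoms", "eq", "daily-activity-only"),
         then = act_assert("nyha_class", "III")),
    rule("nyha_class_IV", 2L, "referral_criteria",
         cnd_atom("nyha_symptoms", "eq", "at-rest"),
         then = act_assert("nyha_class", "IV")),
    # level 3: diagnosis confirmation
    rule("dx_verified", 3L, "referral_criteria",
         cnd_atom("diagnosis_confirmed", "eq", TRUE),
         then = act_assert("dx_criterion", TRUE),
         else_ = list(act_assert("dx_criterion", FALSE),
                      act_recommend("verify diagnosis with tests and disease history"))),
    rule("disease_permitted", 3L, "referral_criteria",
         cnd_atom("disease_permitted", "eq", TRUE),
         then = act_assert("disease_criterion", TRUE),
         else_ = act_assert("disease_criterion", FALSE)),
    rule("diagnosis_criteria", 3L, "referral_criteria",
         cnd_all(cnd_atom("dx_criterion", "eq", TRUE),
                 cnd_atom("disease_criterion", "eq", TRUE)),
         then = act_assert("diagnosis_criteria_met", TRUE),
         else_ = act_assert("diagnosis_criteria_met", FALSE)),
    # level 4: COPD-specific referral criteria
    rule("fev1_flag", 4L, "referral_criteria",
         cnd_atom("fev1_pct", fev1_comparator, fev1_threshold),
         then = act_assert("FEV1_flag", TRUE),
         else_ = act_assert("FEV1_flag", FALSE)),
    rule("nyha_advanced", 4L, "referral_criteria",
         cnd_atom("nyha_class", "in_set", c("III", "IV")),
         then = act_assert("nyha_advanced", TRUE),
         else_ = act_assert("nyha_advanced", FALSE)),
    rule("copd_referral", 4L, "referral_criteria",
         cnd_all(cnd_atom("FEV1_flag", "eq", TRUE),
                 cnd_atom("dyspnea_history", "eq", TRUE),
                 cnd_atom("recurrent_hospitalization", "eq", TRUE),
                 cnd_atom("nyha_advanced", "eq", TRUE)),
         then = list(act_assert("referral_criteria_met", TRUE),
                     act_recommend("the patient has the criteria of referral")),
         else_ = list(act_assert("referral_criteria_met", FALSE),
                      act_alert("COPD referral criteria not met")))
  )
  knowledge_pack(
    name = "imamltx-referral",
    version = "1.0",
    facts = facts,
    rules = rules,
    conclusions = c("referral-criteria-met" = "referral_criteria_met",
                    "general-criteria-met" = "general_criteria_met",
                    "diagnosis-confirmed" = "diagnosis_criteria_met"),
    metadata = list(
      disease_coverage = "COPD",
      parameters = list(age_min = age_min, age_max = age_max,
                        fev1_threshold = fev1_threshold,
                        fev1_comparator = fev1_comparator),
      notes = paste("Referral-investigation rules across four decision levels;",
                    "the FEV1 comparator/threshold and age band are pack",
                    "parameters, not engine behaviour.")
    )
  )
}
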