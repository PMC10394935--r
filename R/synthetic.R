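#' Cohort specification
#'
#' Parameters of the synthetic referral-cohort generator. The defaults are
#' the published 59-patient cohort composition: status mix (referred 3,
#' preassessment 3, referred to committee 2, waiting list 44, transplanted 7)
#' and blood-group mix (O+ 19, O- 5, A+ 5, A- 2, B+ 10, B- 3, AB+ 10, AB- 5),
#' both as proportions of 59.
#'
#' @param n Cohort size.
#' @param prevalence Probability that a patient truly meets the COPD referral
#'   criteria (the published evaluation cohort had 37/59).
#' @param missing_rate Probability that each eligibility-relevant fact is
#'   blanked to unknown (after gold labelling).
#' @param status_mix Named probability vector over [patient_statuses()].
#' @param blood_mix Named probability vector over [blood_groups()].
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An `ltx_cohort_spec`.
#' @export
cohort_spec <- function(n = 59, prevalence = 37 / 59, missing_rate = 0,
                        status_mix = c(referred = 3, preassessment = 3,
                                       referred_to_committee = 2,
                                       waiting_list = 44, transplanted = 7) / 59,
                        blood_mix = c("O+" = 19, "O-" = 5, "A+" = 5, "A-" = 2,
                                      "B+" = 10, "B-" = 3, "AB+" = 10,
                                      "AB-" = 5) / 59,
                        seed = 1L) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!setequal(names(status_mix), patient_statuses()) ||
      abs(sum(status_mix) - 1) > 1e-8 || any(status_mix < 0)) {
    stop("status_mix must be a probability vector over the five statuses")
  }
  if (!setequal(names(blood_mix), blood_groups()) ||
      abs(sum(blood_mix) - 1) > 1e-8 || any(blood_mix < 0)) {
    stop("blood_mix must be a probability vector over the eight blood groups")
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 missing_rate = missing_rate, status_mix = status_mix,
                 blood_mix = blood_mix, seed = as.integer(seed)),
            class = "ltx_cohort_spec")
}

# Independent gold-label oracle: straight-line evaluation of the COPD
# referral conjunction on raw generated values. Deliberately duplicates the
# pack's logic in plain arithmetic, with no condition objects and no engine,
# so engine-vs-oracle is a genuine two-implementation comparison.
#' COPD referral gold-label oracle
#'
#' Direct evaluation of the referral conjunction on raw fact values: FEV1
#' above the threshold (as encoded in the bundled pack), a history of severe
#' dyspnea, recurrent hospitalization, and NYHA class III or IV (symptoms
#' during daily activity, or at rest).
#'
#' @param fev1_pct FEV1 percent predicted.
#' @param dyspnea,hospitalization Logical flags.
#' @param nyha_symptoms Symptom description string.
#' @param fev1_threshold,fev1_gt Threshold and direction mirroring the pack
#'   parameters.
#' @return `TRUE`/`FALSE`.
#' @export
referral_oracle <- function(fev1_pct, dyspnea, hospitalization, nyha_symptoms,
                            fev1_threshold = 35, fev1_gt = TRUE) {
  fev1_ok <- if (fev1_gt) fev1_pct > fev1_threshold else fev1_pct < fev1_threshold
  nyha_ok <- nyha_symptoms == "daily-activity-only" || nyha_symptoms == "at-rest"
  isTRUE(fev1_ok) && isTRUE(dyspnea) && isTRUE(hospitalization) && isTRUE(nyha_ok)
}

#' Generate a synthetic referral cohort with gold labels
#'
#' Draws demographics, status and blood group from the spec's mixes, then
#' constructs the four COPD eligibility facts so that each patient is truly
#' eligible with probability `prevalence`: an eligible patient satisfies all
#' four criteria; an ineligible one has a uniformly chosen non-empty subset of
#' them violated. Gold labels are computed by [referral_oracle()] *before*
#' a fraction `missing_rate` of the eligibility-relevant facts (`fev1_pct`,
#' `dyspnea_history`, `recurrent_hospitalization`, `nyha_symptoms`) is
#' blanked to unknown, so labels stay well-defined and the engine is graded
#' on abstention, not forced guesses. Deterministic given the spec's seed.
#'
#' @param spec An [cohort_spec()].
#' @return List with `records` (list of [patient_record()]s) and
#'   `gold_labels` (named logical vector keyed by patient id).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "ltx_cohort_spec"))
  rng <- .with_seed(spec$seed)
  on.exit(rng())
  n <- spec$n
  statuses <- sample(names(spec$status_mix), n, replace = TRUE,
                     prob = spec$status_mix)
  bgs <- sample(names(spec$blood_mix), n, replace = TRUE, prob = spec$blood_mix)
  sexes <- sample(c("male", "female"), n, replace = TRUE, prob = c(28, 31) / 59)
  ages <- round(stats::runif(n, 18, 64))
  eligible <- stats::runif(n) < spec$prevalence
  records <- vector("list", n)
  gold <- logical(n)
  ids <- sprintf("P%04d", seq_len(n))
  for (i in seq_len(n)) {
    if (eligible[i]) {
      fev1 <- round(stats::runif(1, 36, 80), 1)
      dysp <- TRUE; hosp <- TRUE
      nyha <- sample(c("daily-activity-only", "at-rest"), 1)
    } else {
      # violate a uniformly chosen non-empty subset of the four criteria
      viol <- logical(4)
      while (!any(viol)) viol <- stats::runif(4) < 0.5
      fev1 <- if (viol[1]) round(stats::runif(1, 15, 35), 1)
              else round(stats::runif(1, 36, 80), 1)
      dysp <- !viol[2]
      hosp <- !viol[3]
      nyha <- if (viol[4]) sample(c("none", "normal-activity"), 1)
              else sample(c("daily-activity-only", "at-rest"), 1)
    }
    gold[i] <- referral_oracle(fev1, dysp, hosp, nyha)
    facts <- list(
      ESLD = stats::runif(1) < 0.9,
      survival_lt_50pct = stats::runif(1) < 0.8,
      advanced_despite_treatment = stats::runif(1) < 0.85,
      diagnosis_confirmed = TRUE,
      disease_permitted = TRUE,
      fev1_pct = fev1,
      dyspnea_history = dysp,
      recurrent_hospitalization = hosp,
      nyha_symptoms = nyha,
      waiting_days = round(stats::runif(1, 0, 700))
    )
    if (spec$missing_rate > 0) {
      for (f in c("fev1_pct", "dyspnea_history", "recurrent_hospitalization",
                  "nyha_symptoms")) {
        if (stats::runif(1) < spec$missing_rate) facts[[f]] <- NA
      }
    }
    records[[i]] <- patient_record(
      patient_id = ids[i], age = ages[i], sex = sexes[i], diagnosis = "COPD",
      blood_group = bgs[i], status = statuses[i], facts = facts)
  }
  list(records = records, gold_labels = stats::setNames(gold, ids))
}

# run code under a local RNG state; returns the restore function
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a synthetic expert content-validity survey
#'
#' Each of `N_experts` rates each item on a 3-point scale; the rating is
#' "essential" (3) with the item's probability, otherwise 1 or 2 uniformly.
#' Per-item essential counts are therefore Binomial(N, p).
#'
#' @param N_experts Panel size.
#' @param essential_prob Per-item probability of an essential rating.
#' @param seed Integer seed.
#' @return Integer matrix `N_experts` x items of ratings in 1..3.
#' @export
generate_survey <- function(N_experts, essential_prob, seed = 1L) {
  stopifnot(N_experts >= 1, all(essential_prob >= 0), all(essential_prob <= 1))
  rng <- .with_seed(seed)
  on.exit(rng())
  k <- length(essential_prob)
  m <- matrix(0L, N_experts, k,
              dimnames = list(NULL, paste0("item_", seq_len(k))))
  for (j in seq_len(k)) {
    ess <- stats::runif(N_experts) < essential_prob[j]
    m[, j] <- ifelse(ess, 3L, sample(1:2, N_experts, replace = TRUE))
  }
  m
}

#' Item-level CVRs from a survey matrix
#'
#' @param responses Matrix from [generate_survey()] (or any respondents x
#'   items rating matrix).
#' @param essential_level Rating counted as "essential".
#' @return Data frame: `item`, `n_e`, `N`, `cvr`.
#' @export
cvr_from_responses <- function(responses, essential_level = 3) {
  N <- nrow(responses)
  n_e <- colSums(responses == essential_level)
  data.frame(item = colnames(responses), n_e = as.integer(n_e), N = N,
             cvr = cvr(as.integer(n_e), N), stringsAsFactors = FALSE)
}

#' Default item probabilities for the 63-item reconstruction
#'
#' A synthetic stand-in for the unavailable per-item expert data: 55 items
#' rated essential with probability 0.99 and 8 with probability 0.25, chosen
#' by binomial tail computation so that with an 8-expert panel and the
#' tabulated critical value (CVR >= 0.75, i.e. at least 7 of 8 essential)
#' the expected retained count is close to 55.
#'
#' @return Numeric vector of length 63.
#' @export
survey_probs_63 <- function() {
  c(rep(0.99, 55), rep(0.25, 8))
}

#' Generate a Likert matrix with a target Cronbach's alpha
#'
#' One-factor model: respondent `i`'s score on every item is
#' `loading * latent_i + noise_ij`, with the common loading solved from the
#' Spearman-Brown relation so the expected standardized alpha equals
#' `target_alpha`; scores are then linearly mapped to the scale, rounded to
#' whole points and clipped. Rounding to a coarse scale attenuates alpha
#' slightly below target.
#'
#' @param n_resp Respondents (>= 2).
#' @param n_items Items (>= 2).
#' @param target_alpha Target reliability in `[0, 1)`.
#' @param scale Integer scale bounds `c(min, max)`.
#' @param seed Integer seed.
#' @return Numeric matrix `n_resp` x `n_items` of scale scores.
#' @export
generate_likert <- function(n_resp, n_items, target_alpha, scale = c(0, 7),
                            seed = 1L) {
  stopifnot(n_resp >= 2, n_items >= 2, length(scale) == 2, scale[1] < scale[2])
  if (is.na(target_alpha) || target_alpha < 0 || target_alpha >= 1) {
    stop("target_alpha must lie in [0, 1); got ", target_alpha)
  }
  # mean inter-item correlation achieving alpha for k items (Spearman-Brown)
  rbar <- target_alpha / (n_items - (n_items - 1) * target_alpha)
  if (rbar >= 1) stop("target alpha ", target_alpha, " infeasible with ",
                      n_items, " items")
  loading <- sqrt(rbar / (1 - rbar))
  rng <- .with_seed(seed)
  on.exit(rng())
  latent <- stats::rnorm(n_resp)
  raw <- loading * latent + matrix(stats::rnorm(n_resp * n_items), n_resp)
  # map to scale: centre at the scale midpoint, sd ~ a sixth of the range
  mid <- mean(scale)
  sd_raw <- sqrt(loading^2 + 1)
  scaled <- mid + (raw / sd_raw) * (scale[2] - scale[1]) / 6
  out <- pmin(pmax(round(scaled), scale[1]), scale[2])
  dimnames(out) <- list(NULL, paste0("item_", seq_len(n_items)))
  out
}
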