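#' Construct a simulation scenario
#'
#' A scenario packages every parameter of the synthetic trial generator:
#' arm structure (eligible patients randomized 1:1 to internet/telephone
#' stratified by unit, plus a noneligible arm at a fixed ratio to the
#' eligible count), per-arm nonresponse (optionally age-dependent on the
#' logit scale), demographic models (right-skewed log-normal age and
#' length-of-stay distributions parameterized by median and quartiles),
#' completion-delay models, and per-question response distributions over
#' the instrument vocabularies (including not-applicable-eligible codes).
#'
#' @param n_eligible number of eligible (randomized) patients.
#' @param noneligible_ratio noneligible arm size as a fraction of
#'   `n_eligible` (default 0.25, i.e. 1:4 noneligible:eligible).
#' @param unit_weights named numeric allocation weights across recruiting
#'   units.
#' @param response_rate named per-arm response probabilities.
#' @param response_age_slope named per-arm logit slope of response on
#'   standardized age; the intercept is calibrated so the marginal
#'   response probability matches `response_rate`.
#' @param age_model per-arm list of `c(median, q25, q75)` in years.
#' @param sex_prob_female named per-arm probability of female sex.
#' @param education_probs per-arm probability vector over levels
#'   `1,2,3,4,REFUSED`.
#' @param los_model per-arm `c(median, q25, q75)` length of stay in days
#'   (truncated at 2).
#' @param delay_model per-arm `c(median, q25, q75)` completion delay in
#'   days postdischarge.
#' @param question_probs named list: question id -> named probability
#'   vector over that question's vocabulary. Q6 is instead a list with
#'   `none` (probability of "None") and `options` (per-option inclusion
#'   probabilities given not "None").
#' @param effect named per-arm shift (probability scale) applied to
#'   favorable-response probabilities; see [inject_effect()].
#' @param incomplete_rate named per-arm probability that a returned
#'   questionnaire has one scored question missing.
#' @param latent_sd standard deviation of an optional per-patient latent
#'   satisfaction propensity (logit shift shared across questions);
#'   0 disables it and questions are independent given arm.
#' @param seed integer seed; fully determines the output.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_eligible = 100,
                         noneligible_ratio = 0.25,
                         unit_weights = c(surgery = 0.2, gastroenterology = 0.2,
                                          hepatology = 0.2, infectious = 0.2,
                                          internal_medicine = 0.2),
                         response_rate = c(internet = 1, telephone = 1,
                                           noneligible = 1),
                         response_age_slope = c(internet = 0, telephone = 0,
                                                noneligible = 0),
                         age_model = rep(list(c(55, 39, 66)), 3),
                         sex_prob_female = c(internet = 0.5, telephone = 0.5,
                                             noneligible = 0.5),
                         education_probs = rep(list(c(0.25, 0.25, 0.25, 0.25, 0)), 3),
                         los_model = rep(list(c(6, 3, 10)), 3),
                         delay_model = rep(list(c(7, 7, 9)), 3),
                         question_probs = default_question_probs(),
                         effect = NULL,
                         incomplete_rate = c(internet = 0, telephone = 0,
                                             noneligible = 0),
                         latent_sd = 0,
                         seed = 1L) {
  arms <- arm_levels()
  name_per_arm <- function(x) {
    if (is.null(names(x))) names(x) <- arms
    x[arms]
  }
  sc <- structure(list(
    n_eligible = as.integer(n_eligible),
    noneligible_ratio = noneligible_ratio,
    unit_weights = unit_weights / sum(unit_weights),
    response_rate = name_per_arm(response_rate),
    response_age_slope = name_per_arm(response_age_slope),
    age_model = name_per_arm(age_model),
    sex_prob_female = name_per_arm(sex_prob_female),
    education_probs = name_per_arm(education_probs),
    los_model = name_per_arm(los_model),
    delay_model = name_per_arm(delay_model),
    question_probs = question_probs,
    effect = effect,
    incomplete_rate = name_per_arm(incomplete_rate),
    latent_sd = latent_sd,
    seed = as.integer(seed)), class = "sim_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  if (sc$n_eligible < 2) stop("n_eligible must be at least 2")
  if (sc$noneligible_ratio < 0) stop("noneligible_ratio must be >= 0")
  if (any(sc$response_rate < 0 | sc$response_rate > 1)) {
    stop("response_rate must lie in [0, 1]")
  }
  if (any(sc$unit_weights < 0)) stop("unit_weights must be nonnegative")
  for (arm in arm_levels()) {
    p <- sc$education_probs[[arm]]
    if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("education_probs for arm '", arm,
           "' must be 5 nonnegative values summing to 1")
    }
  }
  map <- default_scoring_map()
  for (id in names(sc$question_probs)) {
    if (id == "Q6") next
    p <- sc$question_probs[[id]]
    voc <- map[[id]]$vocabulary
    if (!setequal(names(p), voc) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("question_probs for ", id,
           " must be a nonnegative vector over its vocabulary summing to 1")
    }
    if (!is.null(sc$effect)) {
      for (arm in names(sc$effect)) {
        if (!map[[id]]$documentation_only) {
          shift_probs(p[voc], map[[id]]$scores, sc$effect[[arm]])  # errors if invalid
        }
      }
    }
  }
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  n_non <- round(x$noneligible_ratio * x$n_eligible)
  cat("Simulation scenario:", x$n_eligible, "eligible patients (+",
      n_non, "noneligible),", length(x$unit_weights), "units, seed",
      x$seed, "\n")
  cat("  response rates:",
      paste(sprintf("%s %.3f", names(x$response_rate), x$response_rate),
            collapse = ", "), "\n")
  if (!is.null(x$effect)) {
    cat("  effect:", paste(sprintf("%s %+0.3f", names(x$effect),
                                   unlist(x$effect)), collapse = ", "), "\n")
  }
  invisible(x)
}

# shift the favorable-response mass of one question by delta, renormalizing
# the remaining non-applicable-free mass; errors outside [0, 1].
shift_probs <- function(probs, scores, delta) {
  if (delta == 0) return(probs)
  fav <- !is.na(scores) & scores == max(scores, na.rm = TRUE)
  oth <- !is.na(scores) & !fav
  p_fav <- sum(probs[fav])
  p_oth <- sum(probs[oth])
  new_fav <- p_fav + delta
  if (new_fav < 0 || new_fav > p_fav + p_oth + 1e-12) {
    stop("effect shift ", delta, " pushes favorable probability outside [0, ",
         p_fav + p_oth, "]")
  }
  out <- probs
  out[fav] <- if (p_fav > 0) probs[fav] * new_fav / p_fav else new_fav / sum(fav)
  out[oth] <- if (p_oth > 0) probs[oth] * (p_oth - delta) / p_oth else 0
  out
}

#' Shift favorable-response probabilities for one arm
#'
#' Returns a copy of the scenario in which every scored question's
#' favorable-response probability (the mass on top-scoring codes) is
#' shifted by `delta` for the named arm, the remaining non-applicable-free
#' mass being renormalized. The null scenario has no shift.
#'
#' @param scenario a `sim_scenario`.
#' @param arm arm label.
#' @param delta shift on the probability scale; must keep all
#'   probabilities in \[0, 1\].
#' @return the modified `sim_scenario`.
#' @export
inject_effect <- function(scenario, arm, delta) {
  if (!arm %in% arm_levels()) stop("unknown arm '", arm, "'")
  if (delta == 0) return(scenario)
  eff <- scenario$effect
  if (is.null(eff)) eff <- list()
  eff[[arm]] <- delta
  scenario$effect <- eff
  validate_scenario(scenario)
}

# log-normal sampler matched to (median, q25, q75); clamped to [lo, hi]
rlnorm_quartiles <- function(n, q, lo = -Inf, hi = Inf) {
  meanlog <- log(q[1])
  sdlog <- log(q[3] / q[2]) / (2 * stats::qnorm(0.75))
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), lo), hi)
}

# responder indicator with marginal rate p and logit slope on standardized
# age; the intercept is solved numerically on the realized ages.
draw_responder <- function(age, p, slope) {
  n <- length(age)
  if (n == 0) return(logical(0))
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  if (slope == 0) return(stats::runif(n) < p)
  z <- (age - mean(age)) / max(stats::sd(age), 1e-9)
  a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * z)) - p,
                      c(-30, 30))$root
  stats::runif(n) < stats::plogis(a + slope * z)
}

# sample one question for n patients; latent is a per-patient logit shift
# on the favorable-vs-rest split (0 = plain multinomial sampling).
sample_question <- function(n, probs, scores, latent = NULL) {
  voc <- names(probs)
  if (is.null(latent) || all(latent == 0)) {
    return(sample(voc, n, replace = TRUE, prob = probs))
  }
  na_set <- is.na(scores)
  fav <- !na_set & scores == max(scores, na.rm = TRUE)
  oth <- !na_set & !fav
  p_na <- sum(probs[na_set])
  p_fav_cond <- sum(probs[fav]) / max(1 - p_na, 1e-12)
  out <- character(n)
  u <- stats::runif(n)
  is_na <- u < p_na
  if (any(is_na)) {
    out[is_na] <- sample(voc[na_set], sum(is_na), replace = TRUE,
                         prob = probs[na_set])
  }
  rest <- !is_na
  p_i <- stats::plogis(stats::qlogis(min(max(p_fav_cond, 1e-9), 1 - 1e-9)) +
                         latent[rest])
  take_fav <- stats::runif(sum(rest)) < p_i
  idx <- which(rest)
  if (any(take_fav)) {
    out[idx[take_fav]] <- sample(voc[fav], sum(take_fav), replace = TRUE,
                                 prob = probs[fav])
  }
  if (any(!take_fav)) {
    if (sum(oth) == 0) {
      out[idx[!take_fav]] <- sample(voc[fav], sum(!take_fav), replace = TRUE,
                                    prob = probs[fav])
    } else {
      out[idx[!take_fav]] <- sample(voc[oth], sum(!take_fav), replace = TRUE,
                                    prob = probs[oth])
    }
  }
  out
}

sample_q6 <- function(n, model) {
  none <- stats::runif(n) < model$none
  opts <- names(model$options)
  sel <- matrix(stats::runif(n * length(opts)) <
                  rep(model$options, each = n), nrow = n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (none[i]) {
      out[i] <- "None"
    } else {
      chosen <- opts[sel[i, ]]
      if (length(chosen) == 0) chosen <- "Prescription(s)"
      out[i] <- paste(chosen, collapse = "|")
    }
  }
  out
}

#' Simulate a synthetic trial cohort
#'
#' Eligible patients are allocated to units by the scenario weights and
#' randomized 1:1 to the internet and telephone arms within unit; the
#' noneligible arm is appended at the scenario ratio. Responder status is
#' drawn from the (possibly age-dependent) response model; question
#' responses are generated only for responders, independently across
#' questions given arm unless a latent propensity is enabled.
#'
#' @param scenario a `sim_scenario`.
#' @param seed optional override of `scenario$seed`.
#' @return list with data frames `profiles` (one row per included
#'   patient) and `responses` (one row per responder), in the layout of
#'   [read_responses()].
#' @export
simulate_cohort <- function(scenario, seed = NULL) {
  validate_scenario(scenario)
  set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
  map <- default_scoring_map()
  units <- names(scenario$unit_weights)

  # eligible arm/unit allocation, stratified 1:1 randomization within unit
  unit_e <- sample(units, scenario$n_eligible, replace = TRUE,
                   prob = scenario$unit_weights)
  arm_e <- character(scenario$n_eligible)
  for (u in units) {
    idx <- which(unit_e == u)
    m <- length(idx)
    if (m == 0) next
    n_int <- m %/% 2 + (m %% 2) * stats::rbinom(1, 1, 0.5)
    pick <- sample(idx, n_int)
    arm_e[pick] <- "internet"
    arm_e[setdiff(idx, pick)] <- "telephone"
  }
  n_non <- round(scenario$noneligible_ratio * scenario$n_eligible)
  unit_n <- if (n_non > 0) {
    sample(units, n_non, replace = TRUE, prob = scenario$unit_weights)
  } else character(0)

  arm <- c(arm_e, rep("noneligible", n_non))
  unit <- c(unit_e, unit_n)
  n <- length(arm)
  profiles <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    arm = arm, unit = unit,
    age = NA_real_, sex = NA_character_, education = NA_character_,
    length_of_stay = NA_real_, responder = NA,
    completion_delay = NA_real_, stringsAsFactors = FALSE)

  for (a in arm_levels()) {
    sel <- which(arm == a)
    m <- length(sel)
    if (m == 0) next
    age <- round(rlnorm_quartiles(m, scenario$age_model[[a]], 18, 100))
    profiles$age[sel] <- age
    profiles$sex[sel] <- ifelse(stats::runif(m) < scenario$sex_prob_female[[a]],
                                "female", "male")
    profiles$education[sel] <- sample(education_levels(), m, replace = TRUE,
                                      prob = scenario$education_probs[[a]])
    profiles$length_of_stay[sel] <-
      round(rlnorm_quartiles(m, scenario$los_model[[a]], 2, 365))
    resp <- draw_responder(age, scenario$response_rate[[a]],
                           scenario$response_age_slope[[a]])
    profiles$responder[sel] <- resp
    if (any(resp)) {
      profiles$completion_delay[sel[resp]] <-
        round(rlnorm_quartiles(sum(resp), scenario$delay_model[[a]], 0, 42))
    }
  }

  # question responses for responders, arm by arm
  resp_idx <- which(profiles$responder)
  responses <- data.frame(patient_id = profiles$patient_id[resp_idx],
                          stringsAsFactors = FALSE)
  for (id in names(map)) responses[[id]] <- NA_character_
  for (a in arm_levels()) {
    rows <- which(profiles$arm[resp_idx] == a)
    m <- length(rows)
    if (m == 0) next
    latent <- if (scenario$latent_sd > 0) {
      stats::rnorm(m, 0, scenario$latent_sd)
    } else NULL
    delta <- if (!is.null(scenario$effect)) scenario$effect[[a]] else NULL
    for (id in names(map)) {
      if (id == "Q6") {
        responses[[id]][rows] <- sample_q6(m, scenario$question_probs$Q6)
        next
      }
      probs <- scenario$question_probs[[id]][map[[id]]$vocabulary]
      scores <- map[[id]]$scores
      if (!is.null(delta) && !map[[id]]$documentation_only) {
        probs <- shift_probs(probs, scores, delta)
      }
      responses[[id]][rows] <- sample_question(
        m, probs, scores,
        latent = if (map[[id]]$documentation_only) NULL else latent)
    }
    # knock out one scored question for a fraction of returned questionnaires
    ir <- scenario$incomplete_rate[[a]]
    if (ir > 0) {
      hit <- rows[stats::runif(m) < ir]
      scored <- question_ids(map, scored_only = TRUE)
      for (i in hit) responses[[sample(scored, 1)]][i] <- NA_character_
    }
  }
  list(profiles = profiles, responses = responses)
}

#' Per-question response probabilities of a generic balanced scenario
#'
#' A neutral default: three quarters of the mass on the favorable code,
#' small not-applicable mass where the vocabulary allows it.
#'
#' @return named list of probability vectors, plus the Q6 model.
#' @export
default_question_probs <- function() {
  map <- default_scoring_map()
  out <- list()
  for (id in names(map)) {
    if (id == "Q6") {
      out$Q6 <- list(none = 0.05,
                     options = c("Prescription(s)" = 0.85,
                                 "Discharge summary" = 0.12,
                                 "Letter for primary care physician" = 0.12,
                                 "Nursing discharge notes" = 0.05,
                                 "Information booklet(s)" = 0.10,
                                 "Appointment for a next hospitalization" = 0.08,
                                 "Appointment for your next consultation" = 0.40,
                                 "Appointment for your complementary test(s)" = 0.15,
                                 "Other, specify" = 0.05))
      next
    }
    d <- map[[id]]
    k <- length(d$vocabulary)
    if (d$documentation_only) {
      p <- rep(1 / k, k)
    } else {
      na_set <- is.na(d$scores)
      fav <- !na_set & d$scores == max(d$scores, na.rm = TRUE)
      p <- numeric(k)
      p[na_set] <- 0.05 / max(sum(na_set), 1)
      rest <- 1 - sum(p)
      p[fav] <- 0.75 * rest / sum(fav)
      oth <- !na_set & !fav
      p[oth] <- 0.25 * rest / sum(oth)
    }
    names(p) <- d$vocabulary
    out[[id]] <- p
  }
  out
}

#' The packaged trial scenario
#'
#' A scenario whose marginal targets are the trial's printed values: arm
#' sizes 430/437/274 (scaled when `n_eligible` differs from 867), arm
#' response rates 0.391/0.872/0.752, responder-age dependence, per-arm
#' demographics (age, sex, education, length of stay, completion delay)
#' and per-question response distributions matching the reported
#' proportions, including the not-applicable rates implied by the printed
#' denominators (737, 720 and 719 out of 755 for Q11C, Q11E and Q7).
#' Splits the report does not print (Q11D, the highly/satisfied split of
#' Q7) are fixed defaults chosen to be consistent with the reported score
#' medians and item ordering.
#'
#' @param n_eligible eligible patients (default 867); the noneligible arm
#'   scales at the observed 274/867 ratio.
#' @param seed integer seed.
#' @return a `sim_scenario`.
#' @export
default_paper_scenario <- function(n_eligible = 867, seed = 1L) {
  qp <- list(
    Q1 = c("Staff physician of the unit in which you were hospitalized" = 0.75,
           "Yourself" = 0.05, "Your entourage" = 0.03,
           "Your primary care physician" = 0.02, "Other" = 0.15),
    Q2 = c(Yes = 664, No = 91) / 755,
    Q3 = c(Yes = 354, No = 401) / 755,
    Q4 = c(Yes = 699, No = 56) / 755,
    Q5 = c(Yes = 685, No = 70) / 755,
    Q6 = default_question_probs()$Q6,
    Q7 = c("Highly satisfied" = 264, "Satisfied" = 260,
           "Poorly satisfied" = 67, "Not at all satisfied" = 13,
           "No information given" = 115, "Not concerned" = 36) / 755,
    Q8 = c(Yes = 0.15, No = 0.85),
    Q9 = c("Yes" = 453, "No" = 177, "I don't know" = 125,
           "I don't have a primary care physician" = 0) / 755,
    Q10 = c(Yes = 675, No = 80) / 755,
    Q11A = c("Well planned" = 642, "A sense of haste, upheaval" = 113) / 755,
    Q11B = c(Relieved = 651, Anxious = 104) / 755,
    Q11C = c(Reasonable = 676, "Too long" = 61, "Not concerned" = 18) / 755,
    Q11D = c(Reasonable = 340, "Too long" = 151, "Not concerned" = 264) / 755,
    Q11E = c(Yes = 70, No = 650, "Not concerned" = 35) / 755,
    Q11F = c(Sufficient = 602, Insufficient = 153) / 755,
    Q11G = c(Sufficient = 683, Insufficient = 72) / 755)
  sim_scenario(
    n_eligible = n_eligible,
    noneligible_ratio = 274 / 867,
    unit_weights = c(surgery = 406, gastroenterology = 194, hepatology = 194,
                     infectious = 194, internal_medicine = 153) / 1141,
    response_rate = c(internet = 168 / 430, telephone = 381 / 437,
                      noneligible = 206 / 274),
    response_age_slope = c(internet = 0.4, telephone = 0.4,
                           noneligible = 0.4),
    age_model = list(internet = c(51, 36, 63), telephone = c(52, 34, 64),
                     noneligible = c(65, 52, 74)),
    sex_prob_female = c(internet = 226 / 430, telephone = 209 / 437,
                        noneligible = 156 / 274),
    education_probs = list(
      internet = c(48, 138, 61, 182, 1) / 430,
      telephone = c(47, 139, 68, 182, 1) / 437,
      noneligible = c(128, 88, 21, 37, 0) / 274),
    los_model = list(internet = c(6, 3, 9), telephone = c(6, 3, 10),
                     noneligible = c(7, 3, 11)),
    delay_model = list(internet = c(6, 3, 16), telephone = c(7, 7, 9),
                       noneligible = c(7, 7, 8)),
    question_probs = qp,
    seed = seed)
}

#' Write / read a scenario as JSON
#'
#' @param scenario a `sim_scenario`.
#' @param path JSON file path.
#' @return `write_scenario`: `path`, invisibly; `read_scenario`: the
#'   `sim_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  # jsonlite drops names on atomic vectors; listify so codes keep their keys
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(scenario)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("response_rate", "response_age_slope", "sex_prob_female",
              "incomplete_rate", "unit_weights")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  for (f in c("age_model", "los_model", "delay_model", "education_probs")) {
    raw[[f]] <- lapply(raw[[f]], unlist)
  }
  qp <- lapply(raw$question_probs, function(q) {
    if (is.list(q) && !is.null(q$options)) {
      list(none = q$none, options = unlist(q$options))
    } else unlist(q)
  })
  raw$question_probs <- qp
  raw$effect <- if (length(raw$effect)) raw$effect else NULL
  sc <- structure(raw, class = "sim_scenario")
  validate_scenario(sc)
}
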