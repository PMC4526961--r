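# percentages are always recomputed from counts; half-up rounding matches
# the mixed 1-decimal / 2-decimal precision of the study reports
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Response-rate and flow accounting
#'
#' Per-arm and per-unit counts of included patients, responders and
#' nonresponders, with response-rate percentages recomputed from the
#' counts (half-up, 1 decimal per arm/unit, 2 decimals overall). When the
#' responder records are supplied, responders are further split into
#' complete and incomplete questionnaires.
#'
#' @param profiles profiles data frame (one row per included patient).
#' @param responses optional responder records, used to count incomplete
#'   questionnaires.
#' @param map a `scoring_map`.
#' @return an object of class `flow_report`: list with `arms`, `units`
#'   data frames and an `overall` list.
#' @export
response_rate_report <- function(profiles, responses = NULL,
                                 map = default_scoring_map()) {
  incomplete_ids <- character(0)
  if (!is.null(responses)) {
    parts <- completeness_filter(responses, map)
    incomplete_ids <- parts$excluded$patient_id
  }
  arm_rows <- list()
  for (a in arm_levels()) {
    sel <- profiles$arm == a
    inc <- sum(sel)
    if (inc == 0) {
      warning("arm '", a, "' has no included patients; omitted from report")
      next
    }
    resp <- sum(profiles$responder[sel])
    n_inc_q <- sum(profiles$patient_id[sel] %in% incomplete_ids)
    arm_rows[[a]] <- data.frame(
      arm = a, included = inc, responders = resp,
      nonresponders = inc - resp,
      complete = resp - n_inc_q, incomplete = n_inc_q,
      response_rate_pct = round_half_up(100 * resp / inc, 1),
      stringsAsFactors = FALSE)
  }
  units <- unique(profiles$unit)
  unit_rows <- lapply(units, function(u) {
    sel <- profiles$unit == u
    data.frame(unit = u, included = sum(sel),
               responders = sum(profiles$responder[sel]),
               response_rate_pct =
                 round_half_up(100 * mean(profiles$responder[sel]), 1),
               contribution_pct =
                 round_half_up(100 * sum(sel) / nrow(profiles), 2),
               stringsAsFactors = FALSE)
  })
  overall <- list(
    included = nrow(profiles),
    responders = sum(profiles$responder),
    incomplete = length(incomplete_ids),
    response_rate_pct = round_half_up(
      100 * sum(profiles$responder) / nrow(profiles), 2))
  structure(list(arms = do.call(rbind, arm_rows),
                 units = do.call(rbind, unit_rows),
                 overall = overall),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat(sprintf("Flow: %d included, %d responders (%.2f%%), %d incomplete\n",
              x$overall$included, x$overall$responders,
              x$overall$response_rate_pct, x$overall$incomplete))
  print(x$arms, row.names = FALSE)
  invisible(x)
}

#' Packaged per-question report definitions
#'
#' The notable response category reported for each question, mirroring
#' the descriptive results of the study (informed of discharge
#' modalities, not consulted, time respected, waiting time reasonable, no
#' administrative difficulties, no explanations received, primary care
#' physician not informed / informed-status unknown, has the unit's phone
#' number, discharge well planned, anxious about returning home, lacked
#' information, staff insufficiently available).
#'
#' @return data frame with columns `question`, `label` and list column
#'   `codes` (the counted response codes).
#' @export
item_proportion_definitions <- function() {
  d <- list(
    list("Q2", "informed_of_discharge_modalities", "Yes"),
    list("Q3", "not_consulted_for_date_time", "No"),
    list("Q4", "date_time_no_problem", "Yes"),
    list("Q5", "time_respected", "Yes"),
    list("Q11C", "document_waiting_time_reasonable", "Reasonable"),
    list("Q11D", "transport_waiting_time_reasonable", "Reasonable"),
    list("Q11E", "no_administrative_difficulties", "No"),
    list("Q7", "explanations_poor_or_unsatisfactory",
         c("Poorly satisfied", "Not at all satisfied")),
    list("Q7", "no_explanations_received", "No information given"),
    list("Q9", "pcp_not_informed", "No"),
    list("Q9", "pcp_informed_unknown", "I don't know"),
    list("Q10", "has_unit_phone_number", "Yes"),
    list("Q11A", "discharge_well_planned", "Well planned"),
    list("Q11B", "anxious_about_return", "Anxious"),
    list("Q11F", "lacked_information", "Insufficient"),
    list("Q11G", "staff_insufficiently_available", "Insufficient"))
  data.frame(question = vapply(d, `[[`, "", 1),
             label = vapply(d, `[[`, "", 2),
             codes = I(lapply(d, `[[`, 3)),
             stringsAsFactors = FALSE)
}

#' Descriptive proportions per question
#'
#' For each packaged report category, the proportion of responders giving
#' that response, with not-applicable answers ("Not concerned", "I don't
#' have a primary care physician") excluded from the denominator and
#' counted separately.
#'
#' @param responses data frame of complete responder records.
#' @param map a `scoring_map`.
#' @param definitions report categories; see
#'   [item_proportion_definitions()].
#' @return data frame: `question`, `label`, `numerator`, `denominator`,
#'   `excluded_na`, `percentage` (half-up, 1 decimal; `NA` and
#'   `undefined = TRUE` when no responder is concerned).
#' @export
item_proportions <- function(responses, map = default_scoring_map(),
                             definitions = item_proportion_definitions()) {
  rows <- lapply(seq_len(nrow(definitions)), function(i) {
    id <- definitions$question[i]
    codes <- definitions$codes[[i]]
    d <- map[[id]]
    x <- responses[[id]]
    x <- x[!is.na(x)]
    na_codes <- d$vocabulary[is.na(d$scores) & !d$documentation_only]
    excluded <- sum(x %in% na_codes)
    denom <- length(x) - excluded
    num <- sum(x %in% codes)
    data.frame(question = id, label = definitions$label[i],
               numerator = num, denominator = denom,
               excluded_na = excluded,
               percentage = if (denom > 0) {
                 round_half_up(100 * num / denom, 1)
               } else NA_real_,
               undefined = denom == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Cohort characteristics summary with responder comparisons
#'
#' Per arm and responder status: counts, sex split, median (IQR) age and
#' length of stay, and education-level counts with percentages. Tests
#' compare responders with nonresponders over all arms: Fisher's exact
#' test for sex, Mann-Whitney-Wilcoxon for age, length of stay, and
#' education treated as a 4-level ordinal variable (refusals excluded).
#'
#' @param profiles profiles data frame.
#' @return an object of class `characteristics_table`: list with
#'   `summary` and `tests` data frames.
#' @export
characteristics_table <- function(profiles) {
  groups <- list(all = rep(TRUE, nrow(profiles)))
  for (a in arm_levels()) groups[[a]] <- profiles$arm == a
  rows <- list()
  for (g in names(groups)) {
    for (st in c("total", "responders", "nonresponders")) {
      sel <- groups[[g]] & switch(st, total = TRUE,
                                  responders = profiles$responder,
                                  nonresponders = !profiles$responder)
      if (sum(sel) == 0) next
      age <- med_iqr(profiles$age[sel])
      los <- med_iqr(profiles$length_of_stay[sel])
      edu <- vapply(education_levels(),
                    function(l) sum(profiles$education[sel] == l), 0L)
      rows[[length(rows) + 1]] <- data.frame(
        arm = g, status = st, n = sum(sel),
        male = sum(profiles$sex[sel] == "male"),
        female = sum(profiles$sex[sel] == "female"),
        age_median = age[1], age_q25 = age[2], age_q75 = age[3],
        los_median = los[1], los_q25 = los[2], los_q75 = los[3],
        edu_1 = edu[1], edu_2 = edu[2], edu_3 = edu[3], edu_4 = edu[4],
        edu_refused = edu[5],
        stringsAsFactors = FALSE)
    }
  }
  resp <- profiles$responder
  tests <- list()
  sex_tab <- table(factor(profiles$sex, c("male", "female")),
                   factor(resp, c(TRUE, FALSE)))
  if (any(rowSums(sex_tab) == 0) || any(colSums(sex_tab) == 0)) {
    tests$sex <- data.frame(variable = "sex", test = "fisher_exact",
                            p = NA_real_, degenerate = TRUE)
  } else {
    tr <- fisher_exact(sex_tab)
    tests$sex <- data.frame(variable = "sex", test = "fisher_exact",
                            p = tr$p_value, degenerate = FALSE)
  }
  for (v in c("age", "length_of_stay")) {
    x <- profiles[[v]][resp]
    y <- profiles[[v]][!resp]
    if (length(x) && length(y)) {
      tr <- mann_whitney(x, y)
      tests[[v]] <- data.frame(variable = v, test = "mann_whitney",
                               p = tr$p_value, degenerate = tr$degenerate)
    }
  }
  edu_num <- suppressWarnings(as.numeric(profiles$education))
  keep <- !is.na(edu_num)
  if (sum(keep & resp) && sum(keep & !resp)) {
    tr <- mann_whitney(edu_num[keep & resp], edu_num[keep & !resp])
    tests$education <- data.frame(variable = "education (ordinal, refusals excluded)",
                                  test = "mann_whitney", p = tr$p_value,
                                  degenerate = tr$degenerate)
  }
  structure(list(summary = do.call(rbind, rows),
                 tests = do.call(rbind, tests)),
            class = "characteristics_table")
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat("Cohort characteristics (responders vs nonresponders)\n")
  print(x$summary, row.names = FALSE)
  cat("\nTests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

# spread a block-constant code vector across positions with a fixed
# stride permutation, so fixture counts are not aligned with arm blocks
stride_perm <- function(n, s) order(((seq_len(n) - 1) * s) %% n)

fixture_quantile_fill <- function(m, q, lo, hi) {
  sdlog <- log(q[3] / q[2]) / (2 * stats::qnorm(0.75))
  round(pmin(pmax(stats::qlnorm(stats::ppoints(m), log(q[1]), sdlog), lo), hi))
}

#' Deterministic fixture cohort with the study's printed marginal counts
#'
#' Unlike the stochastic simulator, this generator materializes a cohort
#' whose marginal counts equal the published ones exactly: arm sizes
#' 430/437/274 with 168/381/206 responders, the per-arm sex and education
#' splits, and per-question response counts (e.g. Q11C 676 "Reasonable" /
#' 61 "Too long" / 18 "Not concerned"). It exists for bit-exact
#' verification of flow accounting and proportion reporting; joint
#' distributions across questions are synthetic (counts are interleaved
#' deterministically) and carry no information.
#'
#' @return list with `profiles` and `responses` data frames.
#' @export
paper_fixture_cohort <- function() {
  arm_n <- c(internet = 430, telephone = 437, noneligible = 274)
  resp_n <- c(internet = 168, telephone = 381, noneligible = 206)
  sex_counts <- list(   # male/female for responders, then nonresponders
    internet = list(r = c(79, 89), n = c(125, 137)),
    telephone = list(r = c(198, 183), n = c(30, 26)),
    noneligible = list(r = c(88, 118), n = c(30, 38)))
  edu_counts <- list(   # levels 1-4 + refused
    internet = list(r = c(17, 51, 25, 75, 0), n = c(31, 87, 36, 107, 1)),
    telephone = list(r = c(38, 121, 62, 160, 0), n = c(9, 18, 6, 22, 1)),
    noneligible = list(r = c(97, 61, 16, 32, 0), n = c(31, 27, 5, 5, 0)))
  age_q <- list(internet = list(r = c(55, 38, 63), n = c(48, 34, 62)),
                telephone = list(r = c(52, 36, 64), n = c(47, 30, 66)),
                noneligible = list(r = c(66, 55, 75), n = c(62, 49, 72)))
  los_q <- list(internet = list(r = c(5.5, 3, 9), n = c(6, 3, 9)),
                telephone = list(r = c(6, 3, 10), n = c(8, 3, 10)),
                noneligible = list(r = c(7, 3, 12), n = c(7, 3, 9)))
  delay_q <- list(internet = c(6, 3, 16), telephone = c(7, 7, 9),
                  noneligible = c(7, 7, 8))
  units <- c("surgery", "gastroenterology", "hepatology", "infectious",
             "internal_medicine")

  profs <- list()
  for (a in names(arm_n)) {
    n <- arm_n[[a]]
    r <- resp_n[[a]]
    status <- c(rep(TRUE, r), rep(FALSE, n - r))
    sex <- c(rep(c("male", "female"), sex_counts[[a]]$r),
             rep(c("male", "female"), sex_counts[[a]]$n))
    edu <- c(rep(education_levels(), edu_counts[[a]]$r),
             rep(education_levels(), edu_counts[[a]]$n))
    age <- c(fixture_quantile_fill(r, age_q[[a]]$r, 18, 100),
             fixture_quantile_fill(n - r, age_q[[a]]$n, 18, 100))
    los <- c(fixture_quantile_fill(r, los_q[[a]]$r, 2, 365),
             fixture_quantile_fill(n - r, los_q[[a]]$n, 2, 365))
    delay <- rep(NA_real_, n)
    delay[seq_len(r)] <- fixture_quantile_fill(r, delay_q[[a]], 0, 42)
    profs[[a]] <- data.frame(
      arm = a, unit = rep_len(units, n), age = age, sex = sex,
      education = edu, length_of_stay = los, responder = status,
      completion_delay = delay, stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, profs)
  profiles <- cbind(patient_id = sprintf("F%05d", seq_len(nrow(profiles))),
                    profiles, stringsAsFactors = FALSE)
  rownames(profiles) <- NULL

  # per-question response counts over the 755 responders
  counts <- list(
    Q1 = c("Staff physician of the unit in which you were hospitalized" = 566,
           "Yourself" = 38, "Your entourage" = 23,
           "Your primary care physician" = 15, "Other" = 113),
    Q2 = c(Yes = 664, No = 91),
    Q3 = c(Yes = 354, No = 401),
    Q4 = c(Yes = 699, No = 56),
    Q5 = c(Yes = 685, No = 70),
    Q6 = c("Prescription(s)" = 564,
           "Prescription(s)|Discharge summary" = 77,
           "Prescription(s)|Letter for primary care physician" = 76,
           "None" = 38),
    Q7 = c("Highly satisfied" = 264, "Satisfied" = 260,
           "Poorly satisfied" = 67, "Not at all satisfied" = 13,
           "No information given" = 115, "Not concerned" = 36),
    Q8 = c(Yes = 113, No = 642),
    Q9 = c("Yes" = 453, "No" = 177, "I don't know" = 125,
           "I don't have a primary care physician" = 0),
    Q10 = c(Yes = 675, No = 80),
    Q11A = c("Well planned" = 642, "A sense of haste, upheaval" = 113),
    Q11B = c(Relieved = 651, Anxious = 104),
    Q11C = c(Reasonable = 676, "Too long" = 61, "Not concerned" = 18),
    Q11D = c(Reasonable = 340, "Too long" = 151, "Not concerned" = 264),
    Q11E = c(Yes = 70, No = 650, "Not concerned" = 35),
    Q11F = c(Sufficient = 602, Insufficient = 153),
    Q11G = c(Sufficient = 683, Insufficient = 72))
  n_resp <- sum(resp_n)
  responses <- data.frame(
    patient_id = profiles$patient_id[profiles$responder],
    stringsAsFactors = FALSE)
  strides <- c(2, 3, 4, 6, 7, 8, 9, 11, 12, 13, 14, 16, 17, 18, 19, 21, 22)
  for (k in seq_along(counts)) {
    id <- names(counts)[k]
    stopifnot(sum(counts[[id]]) == n_resp)
    block <- rep(names(counts[[id]]), counts[[id]])
    responses[[id]] <- block[stride_perm(n_resp, strides[k])]
  }
  list(profiles = profiles, responses = responses)
}

#' Run the full reporting pipeline
#'
#' simulate (or read) -> validate -> completeness filter -> score ->
#' flow report, descriptive proportions, characteristics table,
#' percentile tables and arm comparisons. All artifacts are written to
#' `out_dir`; a rerun with the same inputs produces bit-identical score
#' and flow files.
#'
#' @param config list (or path to a JSON file) with elements: exactly one
#'   of `input_csv` (a responses CSV) or `scenario` (a `sim_scenario`,
#'   `"paper"`, or a scenario JSON path); optional `seed`, `alpha`
#'   (default 0.05), `quantile_type` (default 7), `comparisons`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with all computed reports and the vector of
#'   written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  has_csv <- !is.null(config$input_csv)
  has_scn <- !is.null(config$scenario)
  if (has_csv && has_scn) {
    stop("config must give either input_csv or scenario, not both")
  }
  if (!has_csv && !has_scn) stop("config must give input_csv or scenario")
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  qtype <- if (is.null(config$quantile_type)) 7 else config$quantile_type
  map <- default_scoring_map()

  if (has_csv) {
    if (!file.exists(config$input_csv)) {
      stop("input file not found: ", config$input_csv)
    }
    cohort <- read_responses(config$input_csv, map)
  } else {
    sc <- config$scenario
    if (is.character(sc)) {
      sc <- if (identical(sc, "paper")) default_paper_scenario()
            else read_scenario(sc)
    }
    cohort <- simulate_cohort(sc, seed = config$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  parts <- completeness_filter(cohort$responses, map)
  flow <- response_rate_report(cohort$profiles, cohort$responses, map)
  scores <- score_cohort(parts$complete, cohort$profiles, map)
  props <- item_proportions(parts$complete, map)
  chars <- characteristics_table(cohort$profiles)
  cmp <- compare_arms(scores, alpha = alpha, quantile_type = qtype)
  items <- compare_items_within(scores)

  paths <- c(
    flow = file.path(out_dir, "flow.json"),
    scores = file.path(out_dir, "scores.csv"),
    proportions = file.path(out_dir, "item_proportions.csv"),
    percentiles = file.path(out_dir, "percentiles.csv"),
    comparisons = file.path(out_dir, "comparisons.json"),
    characteristics = file.path(out_dir, "characteristics.csv"),
    log = file.path(out_dir, "run.log"))
  jsonlite::write_json(list(arms = flow$arms, units = flow$units,
                            overall = flow$overall),
                       paths["flow"], auto_unbox = TRUE, digits = NA)
  write_scores(scores, paths["scores"])
  utils::write.csv(props, paths["proportions"], row.names = FALSE, na = "")
  utils::write.csv(cmp$percentiles, paths["percentiles"], row.names = FALSE)
  jsonlite::write_json(list(alpha = alpha, alpha_adjusted = cmp$alpha_adjusted,
                            tests = cmp$tests, item_ordering = items),
                       paths["comparisons"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(chars$summary, paths["characteristics"], row.names = FALSE)
  cfg_str <- jsonlite::toJSON(config[setdiff(names(config), "scenario")],
                              auto_unbox = TRUE)
  writeLines(c(
    paste0("dischargesat ", as.character(utils::packageVersion("dischargesat"))),
    paste0("R ", R.version.string),
    paste0("seed: ", if (is.null(config$seed)) "scenario default"
           else config$seed),
    paste0("config: ", cfg_str),
    paste0("config_checksum: ", sum(utf8ToInt(cfg_str))),
    sprintf("included %d, responders %d (%.2f%%), complete %d, incomplete %d",
            flow$overall$included, flow$overall$responders,
            flow$overall$response_rate_pct, nrow(parts$complete),
            nrow(parts$excluded))),
    paths["log"])
  invisible(list(flow = flow, scores = scores, proportions = props,
                 characteristics = chars, comparisons = cmp,
                 item_ordering = items, files = paths))
}
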