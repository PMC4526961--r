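test_that("instrument matches the published score map", {
  map <- default_scoring_map()
  expect_length(map, 17)
  doc <- names(map)[vapply(map, `[[`, FALSE, "documentation_only")]
  expect_setequal(doc, c("Q1", "Q6", "Q8"))
  expect_length(question_ids(map, scored_only = TRUE), 14)

  expect_setequal(item_questions(map, "logistics"),
                  c("Q2", "Q3", "Q4", "Q5", "Q11C", "Q11D", "Q11E"))
  expect_setequal(item_questions(map, "continuity"), c("Q7", "Q9", "Q10"))
  expect_setequal(item_questions(map, "impressions"),
                  c("Q11A", "Q11B", "Q11F", "Q11G"))

  expect_equal(map$Q7$scores[["Satisfied"]], 0.75)
  expect_equal(map$Q7$scores[["Poorly satisfied"]], 0.25)
  expect_equal(map$Q7$scores[["No information given"]], 0)
  expect_true(is.na(map$Q7$scores[["Not concerned"]]))
  expect_equal(map$Q11E$scores[["Yes"]], 0)   # difficulty polarity inverted
  expect_equal(map$Q11E$scores[["No"]], 1)
  expect_equal(map$Q11C$scores[["Reasonable"]], 1)
  expect_true(is.na(map$Q11D$scores[["Not concerned"]]))
  expect_true(is.na(map$Q9$scores[["I don't have a primary care physician"]]))

  # documentation-only questions feed no score; scored responses lie in [0,1]
  for (d in map) {
    if (d$documentation_only) {
      expect_identical(d$item, "none")
      expect_true(all(is.na(d$scores)))
    } else {
      s <- d$scores[!is.na(d$scores)]
      expect_true(length(s) >= 2 && all(s >= 0 & s <= 1))
    }
  }
  expect_error(item_questions(map, "nope"), "unknown item")
})

test_that("instrument JSON export carries every question", {
  js <- jsonlite::fromJSON(scoring_map_json(default_scoring_map()),
                           simplifyVector = FALSE)
  expect_length(js, 17)
  expect_equal(js$Q7$scores$Satisfied, "0.75")
  expect_equal(js$Q9$scores[["I don't have a primary care physician"]], "NA")
})

test_that("responses CSV round-trips field for field", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- write_tiny_cohort(path, n = 10)
  back <- read_responses(path)
  expect_equal(back$profiles, co$profiles)
  expect_equal(back$responses, co$responses)
  # a second write reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("illegal codes and malformed rows are rejected with location", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- write_tiny_cohort(path, n = 4)
  ok <- read_responses(path)
  expect_equal(nrow(ok$responses), sum(co$profiles$responder))

  bad <- co
  bad$responses$Q2[1] <- "maybe"
  write_responses(bad, path)
  expect_error(read_responses(path), "Q2.*'maybe'|'maybe'.*Q2")

  bad <- co
  bad$responses$Q6[1] <- "Prescription(s)|None"
  write_responses(bad, path)
  expect_error(read_responses(path), "'None' is exclusive")

  bad <- co
  bad$profiles$age[2] <- "old"
  suppressWarnings(write_responses(bad, path))
  expect_error(read_responses(path), "age")
})

test_that("completeness partitions on scored questions only", {
  r_complete <- record_df(Q11D = "Not concerned")
  r_missing <- record_df(patient_id = "P2")
  r_missing$Q10 <- NA_character_
  r_docmiss <- record_df(patient_id = "P3")
  r_docmiss$Q1 <- NA_character_
  r_docmiss$Q6 <- NA_character_
  responses <- rbind(r_complete, r_missing, r_docmiss)

  parts <- completeness_filter(responses)
  expect_setequal(parts$complete$patient_id, c("P1", "P3"))
  expect_equal(parts$excluded$patient_id, "P2")

  empty <- responses[0, ]
  parts0 <- completeness_filter(empty)
  expect_equal(nrow(parts0$complete), 0)
  expect_equal(nrow(parts0$excluded), 0)
})

test_that("completeness is monotone in answered questions", {
  map <- default_scoring_map()
  scored <- question_ids(map, scored_only = TRUE)
  set.seed(11)
  for (i in 1:25) {
    rec <- record_df()
    drop <- sample(scored, sample(0:4, 1))
    for (id in drop) rec[[id]] <- NA_character_
    was_complete <- nrow(completeness_filter(rec)$complete) == 1
    # answer one missing question (if any): never complete -> incomplete
    miss <- scored[is.na(unlist(rec[scored]))]
    if (length(miss)) {
      id <- sample(miss, 1)
      rec[[id]] <- sample(map[[id]]$vocabulary, 1)
    }
    now_complete <- nrow(completeness_filter(rec)$complete) == 1
    expect_true(!was_complete || now_complete)
  }
})

test_that("documentation-only questions are tallied, Q6 per option", {
  r1 <- record_df(Q6 = "Prescription(s)", Q8 = "Yes")
  r2 <- record_df(patient_id = "P2",
                  Q6 = "Prescription(s)|Discharge summary", Q8 = "Yes")
  tabs <- tabulate_documentation(rbind(r1, r2))
  q6 <- tabs$Q6
  expect_equal(q6$n[q6$option == "Prescription(s)"], 2)
  expect_equal(q6$n[q6$option == "Discharge summary"], 1)
  q8 <- tabs$Q8
  expect_equal(q8$n[q8$option == "Yes"], 2)
  expect_equal(q8$proportion[q8$option == "Yes"], 1)
  # Q1 options partition the respondents
  expect_equal(sum(tabs$Q1$n), 2)
})

test_that("simulated responses never leave the vocabularies", {
  map <- default_scoring_map()
  co <- simulate_cohort(default_paper_scenario(n_eligible = 300, seed = 9))
  expect_silent(validate_responses(co$responses, map))
  co2 <- simulate_cohort(sim_scenario(n_eligible = 200, latent_sd = 1,
                                      seed = 10))
  expect_silent(validate_responses(co2$responses, map))
})
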