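#' The discharge satisfaction instrument
#'
#' The instrument asks 17 questions about the hospital discharge process,
#' grouped into three items (dimensions): discharge logistics organization
#' (`logistics`: Q2, Q3, Q4, Q5, Q11C, Q11D, Q11E), preplanned posthospital
#' continuity-of-care organization (`continuity`: Q7, Q9, Q10), and the
#' patient's impressions at discharge (`impressions`: Q11A, Q11B, Q11F,
#' Q11G). Three further questions (Q1, Q6, Q8) document the situation only
#' and never enter a score. Each scored response maps to a value in
#' \[0, 1\]; responses such as "Not concerned" or "I don't have a primary
#' care physician" mark the question as not applicable to that patient, and
#' the question is then removed from both the numerator and the denominator
#' of its subscore.
#'
#' @return An object of class `scoring_map`: a named list of question
#'   definitions, each a list with elements `id`, `text`, `item` (one of
#'   `"logistics"`, `"continuity"`, `"impressions"`, `"none"`),
#'   `vocabulary` (ordered legal responses), `scores` (named numeric over
#'   the vocabulary; `NA` means not applicable), `multiselect` and
#'   `documentation_only`.
#' @examples
#' map <- default_scoring_map()
#' map$Q7$scores[["Satisfied"]]   # 0.75
#' map$Q11E$scores[["Yes"]]       # 0: reporting difficulties scores 0
#' @export
default_scoring_map <- function() {
  q <- function(id, text, item, vocabulary, scores, multiselect = FALSE,
                documentation_only = FALSE) {
    names(scores) <- vocabulary
    list(id = id, text = text, item = item, vocabulary = vocabulary,
         scores = scores, multiselect = multiselect,
         documentation_only = documentation_only)
  }
  yn <- c("Yes", "No")
  defs <- list(
    q("Q1", "Who decided when you would be discharged from the hospital?",
      "none",
      c("Staff physician of the unit in which you were hospitalized",
        "Yourself", "Your entourage", "Your primary care physician", "Other"),
      rep(NA_real_, 5), documentation_only = TRUE),
    q("Q2", "Were you informed by a doctor or nurse of the modalities of your discharge?",
      "logistics", yn, c(1, 0)),
    q("Q3", "Were you consulted for the choice of discharge date and time?",
      "logistics", yn, c(1, 0)),
    q("Q4", "Were the discharge date and time compatible with your return home and/or your entourage?",
      "logistics", yn, c(1, 0)),
    q("Q5", "Was the scheduled discharge time respected?",
      "logistics", yn, c(1, 0)),
    q("Q6", "At discharge, what documents were you given concerning your subsequent care?",
      "none",
      c("Prescription(s)", "Discharge summary",
        "Letter for primary care physician", "Nursing discharge notes",
        "Information booklet(s)", "Appointment for a next hospitalization",
        "Appointment for your next consultation",
        "Appointment for your complementary test(s)", "Other, specify",
        "None"),
      rep(NA_real_, 10), multiselect = TRUE, documentation_only = TRUE),
    q("Q7", "What did you think about the information provided by the medical or nursing staff when you received those discharge documents?",
      "continuity",
      c("Highly satisfied", "Satisfied", "Poorly satisfied",
        "Not at all satisfied", "No information given", "Not concerned"),
      c(1, 0.75, 0.25, 0, 0, NA)),
    q("Q8", "Did you meet with a social worker during your hospitalization to discuss the organization of your return home?",
      "none", yn, c(NA_real_, NA_real_), documentation_only = TRUE),
    q("Q9", "Was your primary care physician informed of your hospitalization?",
      "continuity",
      c("Yes", "No", "I don't know", "I don't have a primary care physician"),
      c(1, 0, 0, NA)),
    q("Q10", "Did you have the phone number of the unit in which you were hospitalized?",
      "continuity", yn, c(1, 0)),
    q("Q11A", "At discharge, what did you think about its organization?",
      "impressions", c("Well planned", "A sense of haste, upheaval"), c(1, 0)),
    q("Q11B", "At discharge, what did you think about returning home?",
      "impressions", c("Relieved", "Anxious"), c(1, 0)),
    q("Q11C", "At discharge, what did you think of the time needed to obtain your medical and administrative documents?",
      "logistics", c("Reasonable", "Too long", "Not concerned"), c(1, 0, NA)),
    q("Q11D", "At discharge, what did you think of the time needed for your transportation to arrive?",
      "logistics", c("Reasonable", "Too long", "Not concerned"), c(1, 0, NA)),
    q("Q11E", "At discharge, did you have any difficulties dealing with the administrative discharge formalities?",
      "logistics", c("Yes", "No", "Not concerned"), c(0, 1, NA)),
    q("Q11F", "At discharge, what did you think about the information provided?",
      "impressions", c("Sufficient", "Insufficient"), c(1, 0)),
    q("Q11G", "At discharge, what did you think about the health care team's availability and listening to you?",
      "impressions", c("Sufficient", "Insufficient"), c(1, 0))
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  structure(defs, class = "scoring_map")
}

#' @export
print.scoring_map <- function(x, ...) {
  cat("Discharge satisfaction instrument:", length(x), "questions\n")
  for (d in x) {
    tag <- if (d$documentation_only) "documentation" else d$item
    cat(sprintf("  %-5s [%s] %s\n", d$id, tag, d$text))
  }
  invisible(x)
}

#' Question ids of an instrument
#'
#' @param map a `scoring_map`.
#' @param scored_only if `TRUE`, only score-contributing questions.
#' @return character vector of question ids in instrument order.
#' @export
question_ids <- function(map, scored_only = FALSE) {
  ids <- names(map)
  if (scored_only) {
    ids <- ids[!vapply(map, `[[`, FALSE, "documentation_only")]
  }
  ids
}

#' Questions belonging to one item
#'
#' @param map a `scoring_map`.
#' @param item `"logistics"`, `"continuity"` or `"impressions"`.
#' @return character vector of question ids.
#' @export
item_questions <- function(map, item) {
  items <- c("logistics", "continuity", "impressions")
  if (!item %in% items) {
    stop("unknown item '", item, "'; expected one of: ",
         paste(items, collapse = ", "))
  }
  names(map)[vapply(map, `[[`, "", "item") == item]
}

#' Export the instrument definition as JSON
#'
#' Serializes the full question set (vocabularies, score map, item
#' membership) for audit, with `"NA"` standing for not-applicable scores.
#'
#' @param map a `scoring_map`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
scoring_map_json <- function(map, path = NULL) {
  lst <- lapply(unclass(map), function(d) {
    s <- as.list(ifelse(is.na(d$scores), "NA", as.character(d$scores)))
    names(s) <- d$vocabulary
    d$scores <- s
    d
  })
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# column layout of the responses CSV: profile columns then question columns
profile_columns <- function() {
  c("patient_id", "arm", "unit", "age", "sex", "education",
    "length_of_stay", "responder", "completion_delay")
}

arm_levels <- function() c("internet", "telephone", "noneligible")
education_levels <- function() c("1", "2", "3", "4", "REFUSED")

q6_split <- function(x) strsplit(x, "|", fixed = TRUE)

validate_profiles <- function(profiles) {
  need <- profile_columns()
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profile columns missing: ", paste(miss, collapse = ", "))
  bad <- !profiles$arm %in% arm_levels()
  if (any(bad)) stop("illegal arm value(s) in row(s) ",
                     paste(which(bad), collapse = ", "))
  if (any(profiles$length_of_stay < 2, na.rm = TRUE)) {
    stop("length_of_stay below 2 days: the instrument targets stays of 2 or more days")
  }
  bad_delay <- xor(profiles$responder, !is.na(profiles$completion_delay))
  if (any(bad_delay)) {
    stop("completion_delay must be present exactly for responders; offending row(s): ",
         paste(utils::head(which(bad_delay), 5), collapse = ", "))
  }
  invisible(profiles)
}

#' Validate a table of questionnaire responses
#'
#' Checks every answered code against the question's response vocabulary.
#' `NA` cells mean the question is missing (unanswered). The multiselect
#' question Q6 is encoded as a `|`-joined set of options; `"None"` is
#' exclusive with every other option.
#'
#' @param responses data frame with `patient_id` and one column per
#'   question id.
#' @param map a `scoring_map`.
#' @return `responses`, invisibly; errors name the offending row and column.
#' @export
validate_responses <- function(responses, map) {
  miss <- setdiff(names(map), names(responses))
  if (length(miss)) stop("question columns missing: ", paste(miss, collapse = ", "))
  for (id in names(map)) {
    d <- map[[id]]
    x <- responses[[id]]
    if (d$multiselect) {
      parts <- q6_split(x[!is.na(x)])
      rows <- which(!is.na(x))
      for (k in seq_along(parts)) {
        p <- parts[[k]]
        unknown <- setdiff(p, d$vocabulary)
        if (length(unknown)) {
          stop(sprintf("row %d, column %s: illegal response code '%s'",
                       rows[k], id, unknown[1]))
        }
        if ("None" %in% p && length(p) > 1) {
          stop(sprintf("row %d, column %s: 'None' is exclusive with other options",
                       rows[k], id))
        }
        if (anyDuplicated(p)) {
          stop(sprintf("row %d, column %s: duplicated option", rows[k], id))
        }
      }
    } else {
      bad <- !is.na(x) & !x %in% d$vocabulary
      if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf("row %d, column %s: illegal response code '%s'",
                     i, id, x[i]))
      }
    }
  }
  invisible(responses)
}

#' Read a cohort (profiles + responses) from CSV
#'
#' One row per patient. Profile columns (`patient_id`, `arm`, `unit`,
#' `age`, `sex`, `education`, `length_of_stay`, `responder`,
#' `completion_delay`) are followed by one column per question id; empty
#' cells are missing answers. Nonresponders carry no answers.
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @param map a `scoring_map`; defaults to the packaged instrument.
#' @return a list with data frames `profiles` and `responses` (the latter
#'   restricted to responders, `patient_id` + question columns).
#' @export
read_responses <- function(path, map = default_scoring_map()) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(profile_columns(), names(map))
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("columns missing from ", path, ": ",
                         paste(miss, collapse = ", "))
  profiles <- raw[profile_columns()]
  for (col in c("age", "length_of_stay", "completion_delay")) {
    suppressWarnings(v <- as.numeric(profiles[[col]]))
    bad <- is.na(v) & !is.na(profiles[[col]])
    if (any(bad)) stop(sprintf("row %d, column %s: not a number ('%s')",
                               which(bad)[1], col, profiles[[col]][which(bad)[1]]))
    profiles[[col]] <- v
  }
  profiles$responder <- profiles$responder %in% c("TRUE", "true", "1", "yes")
  validate_profiles(profiles)
  responses <- raw[raw$responder %in% c("TRUE", "true", "1", "yes"),
                   c("patient_id", names(map)), drop = FALSE]
  rownames(responses) <- NULL
  validate_responses(responses, map)
  list(profiles = profiles, responses = responses)
}

#' Write a cohort to CSV (inverse of [read_responses()])
#'
#' @param cohort list with `profiles` and `responses` data frames.
#' @param path output CSV path.
#' @param map a `scoring_map` fixing the question column order.
#' @return `path`, invisibly.
#' @export
write_responses <- function(cohort, path, map = default_scoring_map()) {
  profiles <- cohort$profiles
  responses <- cohort$responses
  qcols <- as.data.frame(matrix(NA_character_, nrow(profiles), length(map)),
                         stringsAsFactors = FALSE)
  names(qcols) <- names(map)
  idx <- match(responses$patient_id, profiles$patient_id)
  if (anyNA(idx)) stop("responses contain patient_id absent from profiles")
  for (id in names(map)) qcols[[id]][idx] <- responses[[id]]
  out <- cbind(profiles[profile_columns()], qcols)
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Partition responses into complete and incomplete records
#'
#' A record is complete when no score-contributing question is missing;
#' not-applicable-eligible answers such as "Not concerned" count as
#' answered, and missing documentation-only questions (Q1, Q6, Q8) never
#' exclude a record. Incomplete questionnaires are excluded from all score
#' analyses but kept for flow accounting.
#'
#' @param responses data frame of responder records.
#' @param map a `scoring_map`.
#' @return list with data frames `complete` and `excluded`.
#' @export
completeness_filter <- function(responses, map = default_scoring_map()) {
  scored <- question_ids(map, scored_only = TRUE)
  if (nrow(responses) == 0) {
    return(list(complete = responses, excluded = responses))
  }
  n_missing <- rowSums(is.na(responses[, scored, drop = FALSE]))
  ok <- n_missing == 0
  list(complete = responses[ok, , drop = FALSE],
       excluded = responses[!ok, , drop = FALSE])
}

#' Frequency tables for the documentation-only questions
#'
#' Q1 (who decided the discharge) and Q8 (social worker met) are tallied
#' over single responses; the multiselect Q6 (documents given) is tallied
#' per checkable option over patients.
#'
#' @param responses data frame of complete responder records.
#' @param map a `scoring_map`.
#' @return named list of data frames (`Q1`, `Q6`, `Q8`) with columns
#'   `option`, `n`, `proportion` (of patients answering the question).
#' @export
tabulate_documentation <- function(responses, map = default_scoring_map()) {
  out <- list()
  for (id in c("Q1", "Q6", "Q8")) {
    d <- map[[id]]
    x <- responses[[id]]
    x <- x[!is.na(x)]
    if (d$multiselect) {
      opts <- unlist(q6_split(x))
      n <- vapply(d$vocabulary, function(o) sum(opts == o), 0L)
    } else {
      n <- vapply(d$vocabulary, function(o) sum(x == o), 0L)
    }
    denom <- length(x)
    out[[id]] <- data.frame(option = d$vocabulary, n = unname(n),
                            proportion = if (denom) unname(n) / denom else NA_real_,
                            stringsAsFactors = FALSE)
  }
  out
}
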