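#' Score one item for a single response record
#'
#' The subscore is the normalized sum of the item's question scores: each
#' question has equal weight, and questions answered with a
#' not-applicable-eligible response ("Not concerned", "I don't have a
#' primary care physician") are removed from both the numerator and the
#' denominator. When every question of the item is not applicable the
#' subscore is undefined and `NA` is returned.
#'
#' @param record one-row data frame (or named list/character vector) of
#'   complete answers.
#' @param item `"logistics"`, `"continuity"` or `"impressions"`.
#' @param map a `scoring_map`.
#' @return the subscore in \[0, 1\], or `NA` if no question applies.
#' @examples
#' map <- default_scoring_map()
#' rec <- list(Q7 = "Satisfied", Q9 = "Yes", Q10 = "No")
#' score_item(rec, "continuity", map)  # (0.75 + 1 + 0) / 3
#' @export
score_item <- function(record, item, map = default_scoring_map()) {
  qs <- item_questions(map, item)
  vals <- vapply(qs, function(id) {
    ans <- record[[id]]
    if (is.null(ans) || is.na(ans)) {
      stop("record is incomplete: ", id, " is missing")
    }
    s <- map[[id]]$scores[match(ans, map[[id]]$vocabulary)]
    if (!ans %in% map[[id]]$vocabulary) {
      stop("illegal response code '", ans, "' for ", id)
    }
    unname(s)
  }, numeric(1))
  k <- sum(!is.na(vals))
  if (k == 0) return(NA_real_)
  sum(vals, na.rm = TRUE) / k
}

#' Total score from the three subscores
#'
#' The total satisfaction score is the arithmetic mean of the three item
#' subscores, defined only when all three are defined.
#'
#' @param logistics,continuity,impressions subscores in \[0, 1\] or `NA`.
#' @return the total score, or `NA` if any subscore is undefined.
#' @export
score_total <- function(logistics, continuity, impressions) {
  (logistics + continuity + impressions) / 3
}

#' Score a cohort of complete response records
#'
#' Vectorized scoring of every record: the three item subscores, the total
#' score, and the per-item counts of applicable questions (the subscore
#' denominators).
#'
#' @param responses data frame of complete responder records
#'   (`patient_id` + question columns).
#' @param profiles optional profiles data frame; when supplied, every
#'   `patient_id` in `responses` must appear in it and the `arm` column is
#'   carried into the result.
#' @param map a `scoring_map`.
#' @return a data frame of class `score_set` with columns `patient_id`,
#'   (`arm`,) `logistics`, `continuity`, `impressions`, `total`,
#'   `n_logistics`, `n_continuity`, `n_impressions`.
#' @export
score_cohort <- function(responses, profiles = NULL,
                         map = default_scoring_map()) {
  n <- nrow(responses)
  items <- c("logistics", "continuity", "impressions")
  out <- data.frame(patient_id = responses$patient_id,
                    stringsAsFactors = FALSE)
  if (!is.null(profiles)) {
    idx <- match(responses$patient_id, profiles$patient_id)
    if (anyNA(idx)) {
      stop("patient_id in responses without a matching profile: ",
           responses$patient_id[which(is.na(idx))[1]])
    }
    out$arm <- profiles$arm[idx]
  }
  for (item in items) {
    qs <- item_questions(map, item)
    smat <- matrix(NA_real_, n, length(qs))
    for (j in seq_along(qs)) {
      id <- qs[j]
      ans <- responses[[id]]
      if (anyNA(ans)) stop("record is incomplete: ", id, " is missing")
      pos <- match(ans, map[[id]]$vocabulary)
      if (anyNA(pos)) {
        stop("illegal response code '", ans[which(is.na(pos))[1]],
             "' for ", id)
      }
      smat[, j] <- map[[id]]$scores[pos]
    }
    k <- rowSums(!is.na(smat))
    sub <- ifelse(k > 0, rowSums(smat, na.rm = TRUE) / k, NA_real_)
    out[[item]] <- sub
    out[[paste0("n_", item)]] <- k
  }
  out$total <- score_total(out$logistics, out$continuity, out$impressions)
  out <- out[c(setdiff(names(out), c("n_logistics", "n_continuity",
                                     "n_impressions", "total")),
               "total", "n_logistics", "n_continuity", "n_impressions")]
  class(out) <- c("score_set", "data.frame")
  out
}

#' @export
print.score_set <- function(x, digits = 2, ...) {
  cat("Satisfaction scores for", nrow(x), "patients\n")
  defined <- !is.na(x$total)
  cat(sprintf("  total defined for %d (%.1f%%); median total %.2f\n",
              sum(defined), 100 * mean(defined),
              stats::median(x$total[defined])))
  NextMethod(x, digits = digits)
}

#' Write a score set to CSV
#'
#' @param scores a `score_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}
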