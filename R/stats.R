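#' @title Nonparametric test battery
#' @description Exact and tie-corrected versions of the three tests used
#'   for arm and item comparisons. Small samples use full enumeration of
#'   the null distribution; larger samples use the normal approximation
#'   with tie-corrected variance and a continuity correction.
#' @name rank-tests
NULL

new_test_result <- function(test_name, statistic, p_value, method,
                            n_per_group, degenerate = FALSE) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, method = method,
                 n_per_group = n_per_group, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test_name, "\n")
  cat(sprintf("  statistic = %g, p = %s (%s)\n", x$statistic,
              format.pval(x$p_value, digits = 4), x$method))
  cat("  n =", paste(x$n_per_group, collapse = ", "),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing, over the hypergeometric null
#' conditional on the margins, the probabilities of all tables no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return a `test_result`; the statistic is the sample odds ratio.
#' @examples
#' fisher_exact(matrix(c(168, 381, 262, 56), 2))  # p << 0.001
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row 1 total
  n2 <- sum(tab[2, ])         # row 2 total
  k <- sum(tab[, 1])          # column 1 total
  support <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_test_result("Fisher's exact test", statistic = or,
                  p_value = min(1, p), method = "exact_enumeration",
                  n_per_group = rowSums(tab))
}

# tie correction term sum(t^3 - t) over tie groups of the pooled sample
tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Two-sided test of identical distributions against a location shift.
#' When the combined sample size is at most `exact_limit` the permutation
#' null of the rank sum is enumerated over all allocations of the pooled
#' values (ties handled by midranks), and the p-value is the probability
#' of a rank sum at least as far from its null mean as observed.
#' Otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction is used.
#'
#' @param x,y nonempty numeric samples.
#' @param exact_limit enumeration cutoff on `length(x) + length(y)`.
#' @return a `test_result`; the statistic is the Mann-Whitney U of `x`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # p = 0.1
#' @export
mann_whitney <- function(x, y, exact_limit = 20) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  m <- length(x)
  n <- length(y)
  N <- m + n
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  U <- r1 - m * (m + 1) / 2
  dev <- abs(r1 - mu)
  if (N <= exact_limit) {
    combos <- utils::combn(N, m)
    sums <- colSums(matrix(r[combos], nrow = m))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    method <- "exact_enumeration"
  } else {
    sigma2 <- m * n * (N + 1) / 12 - m * n * tie_term(r) / (12 * N * (N - 1))
    if (sigma2 <= 0) {
      return(new_test_result("Mann-Whitney-Wilcoxon test", U, 1,
                             "normal_approx_ties", c(m, n), degenerate = TRUE))
    }
    z <- (dev - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx_ties"
  }
  new_test_result("Mann-Whitney-Wilcoxon test", U, p, method, c(m, n))
}

#' Wilcoxon signed rank test for paired differences
#'
#' Zero differences are dropped (reduced-sample convention). For at most
#' `exact_limit` nonzero differences the null distribution of the
#' positive-rank sum is enumerated exactly over all sign assignments (by
#' convolution over the midranks); otherwise the tie-corrected normal
#' approximation with continuity correction is used. An all-zero input is
#' flagged degenerate with p = 1.
#'
#' @param d numeric vector of paired differences.
#' @param exact_limit enumeration cutoff on the number of nonzero
#'   differences.
#' @return a `test_result`; the statistic is the positive-rank sum V.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # p = 0.25
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 24) {
  if (length(d) == 0) stop("empty sample")
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result("Wilcoxon signed rank test", 0, 1,
                           "exact_enumeration", 0, degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  dev <- abs(V - mu)
  if (n <= exact_limit) {
    # null distribution of V by convolution; midranks doubled to integers
    ri <- as.integer(round(2 * r))
    dist <- numeric(sum(ri) + 1)   # index s+1 holds P(2V = s) * 2^n
    dist[1] <- 1
    for (w in ri) {
      shifted <- c(numeric(w), dist[seq_len(length(dist) - w)])
      dist <- dist + shifted
    }
    support <- (seq_along(dist) - 1) / 2
    p <- sum(dist[abs(support - mu) >= dev - 1e-9]) / 2^n
    method <- "exact_enumeration"
  } else {
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term(abs(d)) / 48
    if (sigma2 <= 0) {
      return(new_test_result("Wilcoxon signed rank test", V, 1,
                             "normal_approx_ties", n, degenerate = TRUE))
    }
    z <- (dev - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx_ties"
  }
  new_test_result("Wilcoxon signed rank test", V, p, method, n)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal level.
#' @param k number of comparisons (>= 1).
#' @return `alpha / k`.
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Percentile table of a score sample
#'
#' Quantiles by linear interpolation of order statistics at position
#' h = (n - 1)p + 1 (`type = 7`); the interpolation mode is configurable
#' through `type`. Reported values are rounded to two decimals; the raw
#' quantiles are kept in attribute `"raw"`.
#'
#' @param scores nonempty numeric sample (`NA` removed).
#' @param levels percentile levels in (0, 100).
#' @param group label for the sample.
#' @param type quantile interpolation mode, passed to [stats::quantile()].
#' @return one-row data frame of class `percentile_table` with the group
#'   label and one `p<level>` column per level.
#' @export
percentile_table <- function(scores, levels = c(5, 10, 25, 50, 75, 90, 95),
                             group = "all", type = 7) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("empty sample")
  q <- stats::quantile(scores, probs = levels / 100, type = type,
                       names = FALSE)
  out <- as.data.frame(as.list(round(q, 2)))
  names(out) <- paste0("p", levels)
  out <- cbind(data.frame(group = group, n = length(scores),
                          stringsAsFactors = FALSE), out)
  attr(out, "raw") <- q
  class(out) <- c("percentile_table", "data.frame")
  out
}

#' Compare satisfaction scores between arms
#'
#' For the total score and each subscore, runs the Mann-Whitney-Wilcoxon
#' test for every requested arm pair and reports significance against the
#' Bonferroni-adjusted threshold (the nominal level divided by the number
#' of comparisons per score), together with percentile tables per arm and
#' overall.
#'
#' @param scores a `score_set` with an `arm` column.
#' @param comparisons list of length-2 character vectors of arm labels;
#'   default: telephone vs internet and telephone vs noneligible.
#' @param alpha nominal significance level.
#' @param quantile_type interpolation mode for percentile tables.
#' @return an object of class `arm_comparison`: list with `tests` (data
#'   frame: score, comparison, U, p, adjusted threshold, significant) and
#'   `percentiles` (data frame stacking per-arm and overall tables per
#'   score).
#' @export
compare_arms <- function(scores,
                         comparisons = list(c("telephone", "internet"),
                                            c("telephone", "noneligible")),
                         alpha = 0.05, quantile_type = 7) {
  if (is.null(scores$arm)) stop("score set lacks an 'arm' column")
  arms_present <- unique(scores$arm)
  for (cmp in comparisons) {
    absent <- setdiff(cmp, arms_present)
    if (length(absent)) {
      stop("arm(s) not present: ", paste(absent, collapse = ", "),
           "; available: ", paste(arms_present, collapse = ", "))
    }
  }
  thr <- bonferroni_threshold(alpha, length(comparisons))
  score_cols <- c("total", "logistics", "continuity", "impressions")
  rows <- list()
  pct <- list()
  for (sc in score_cols) {
    vals <- scores[[sc]]
    ok <- !is.na(vals)
    pct[[length(pct) + 1]] <- cbind(score = sc,
                                    percentile_table(vals[ok], group = "all",
                                                     type = quantile_type))
    for (arm in intersect(arm_levels(), arms_present)) {
      sel <- ok & scores$arm == arm
      if (sum(sel) == 0) next
      pct[[length(pct) + 1]] <- cbind(score = sc,
                                      percentile_table(vals[sel], group = arm,
                                                       type = quantile_type))
    }
    for (cmp in comparisons) {
      xa <- vals[ok & scores$arm == cmp[1]]
      xb <- vals[ok & scores$arm == cmp[2]]
      if (length(xa) < 2 || length(xb) < 2) {
        stop("fewer than 2 defined scores in arm(s) of comparison ",
             paste(cmp, collapse = " vs "))
      }
      tr <- mann_whitney(xa, xb)
      rows[[length(rows) + 1]] <- data.frame(
        score = sc, comparison = paste(cmp, collapse = " vs "),
        U = tr$statistic, p = tr$p_value, method = tr$method,
        alpha_adjusted = thr, significant = tr$p_value <= thr,
        stringsAsFactors = FALSE)
    }
  }
  pct_df <- do.call(rbind, lapply(pct, function(p) {
    attr(p, "raw") <- NULL
    class(p) <- "data.frame"
    p
  }))
  structure(list(tests = do.call(rbind, rows), percentiles = pct_df,
                 alpha = alpha, alpha_adjusted = thr),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("Arm comparisons (Mann-Whitney-Wilcoxon, Bonferroni-adjusted alpha =",
      format(x$alpha_adjusted), ")\n")
  print(x$tests, row.names = FALSE)
  cat("\nScore percentiles:\n")
  print(x$percentiles, row.names = FALSE)
  invisible(x)
}

#' Within-patient ordering of the three items
#'
#' Wilcoxon signed rank tests on the paired per-patient differences
#' logistics - continuity and impressions - logistics, with the direction
#' of the median difference. Restricted to patients with all three
#' subscores defined.
#'
#' @param scores a `score_set`.
#' @return data frame with one row per contrast: median difference,
#'   direction, V, p, method, degenerate flag.
#' @export
compare_items_within <- function(scores) {
  ok <- !is.na(scores$logistics) & !is.na(scores$continuity) &
    !is.na(scores$impressions)
  if (sum(ok) < 2) stop("fewer than 2 patients with all subscores defined")
  contrasts <- list(
    c("logistics", "continuity"),
    c("impressions", "logistics")
  )
  rows <- lapply(contrasts, function(ct) {
    d <- scores[[ct[1]]][ok] - scores[[ct[2]]][ok]
    tr <- wilcoxon_signed_rank(d)
    md <- stats::median(d)
    data.frame(contrast = paste(ct[1], "-", ct[2]),
               median_diff = md,
               direction = if (md > 0) ">" else if (md < 0) "<" else "=",
               V = tr$statistic, p = tr$p_value, method = tr$method,
               degenerate = tr$degenerate, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
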