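test_that("Fisher's exact test sums hypergeometric tail correctly", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  r <- fisher_exact(matrix(c(168, 381, 262, 56), 2))
  expect_lt(r$p_value, 0.001)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")

  set.seed(31)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Mann-Whitney exact path matches hand enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 0)
  expect_equal(r$method, "exact_enumeration")

  x <- c(1, 2, 2, 5)
  expect_equal(mann_whitney(x, x)$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")

  # two-sided symmetry under sample swap
  set.seed(32)
  for (i in 1:20) {
    x <- sample(0:3, sample(2:6, 1), replace = TRUE)
    y <- sample(0:3, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
  }
})

test_that("normal approximation tracks the exact test where decisions fall", {
  # the permutation null at N = 16 is discrete in steps of ~0.1, so global
  # agreement to 0.02 is impossible for any continuous approximation; the
  # approximation must instead track the exact p closely in the tail
  # (p <= 0.2) and classify significance at alpha = .05 consistently
  set.seed(33)
  tail_diff <- 0
  agree <- logical(200)
  for (i in 1:200) {
    x <- sample(seq(0, 1, 0.25), 8, replace = TRUE)
    y <- sample(seq(0, 1, 0.25), 8, replace = TRUE)
    pe <- mann_whitney(x, y)$p_value
    pa <- mann_whitney(x, y, exact_limit = 0)$p_value
    if (pe <= 0.2) tail_diff <- max(tail_diff, abs(pe - pa))
    agree[i] <- (pe <= 0.05) == (pa <= 0.05)
  }
  expect_lte(tail_diff, 0.05)
  expect_gte(mean(agree), 0.95)
})

test_that("signed rank test handles zeros, ties and symmetry", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$statistic, 6)

  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)

  r0 <- wilcoxon_signed_rank(c(0, 0))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)

  set.seed(34)
  for (i in 1:20) {
    d <- sample(-3:3, sample(3:8, 1), replace = TRUE)
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_signed_rank(-d)$p_value)
  }
})

test_that("Bonferroni threshold divides the level", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.06, 3), 0.02)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("percentile tables interpolate order statistics", {
  expect_equal(percentile_table(c(0, 1), levels = 50)$p50, 0.5)
  expect_equal(percentile_table(c(0.25, 0.25, 0.5), levels = 10)$p10, 0.25)
  pt <- percentile_table(rep(0.7, 9))
  expect_true(all(unlist(pt[paste0("p", c(5, 10, 25, 50, 75, 90, 95))]) == 0.7))
  expect_error(percentile_table(numeric(0)), "empty")

  set.seed(35)
  x <- runif(40)
  p1 <- percentile_table(x)
  p2 <- percentile_table(sample(x))
  expect_equal(p1, p2)
  v <- unlist(p1[paste0("p", c(5, 10, 25, 50, 75, 90, 95))])
  expect_true(all(diff(v) >= 0))
})

test_that("arm comparison applies the Bonferroni-adjusted threshold", {
  set.seed(36)
  vals <- sample(seq(0, 1, 0.25), 8, replace = TRUE)
  scores <- data.frame(patient_id = sprintf("P%d", 1:16),
                       arm = rep(c("telephone", "internet"), each = 8),
                       logistics = rep(vals, 2), continuity = rep(vals, 2),
                       impressions = rep(vals, 2), total = rep(vals, 2))
  cmp <- compare_arms(scores,
                      comparisons = list(c("telephone", "internet")))
  # identical multisets under both labels: exact symmetry gives p = 1
  expect_true(all(cmp$tests$p == 1))
  expect_equal(unique(cmp$tests$alpha_adjusted), 0.05)

  cmp2 <- compare_arms(rbind(scores,
                             within(scores, {
                               arm <- "noneligible"
                               patient_id <- paste0("N", patient_id)
                             })))
  expect_equal(unique(cmp2$tests$alpha_adjusted), 0.025)
  expect_error(compare_arms(scores), "not present")

  pct <- cmp$percentiles
  expect_true(all(c("all", "telephone", "internet") %in% pct$group))
})

test_that("within-patient item contrasts report direction and significance", {
  n <- 60
  scores <- data.frame(patient_id = sprintf("P%d", 1:n),
                       logistics = rep(0.8, n), continuity = rep(0.5, n),
                       impressions = rep(1, n))
  scores$total <- (scores$logistics + scores$continuity + scores$impressions) / 3
  rep_ <- compare_items_within(scores)
  expect_equal(rep_$direction, c(">", ">"))
  expect_true(all(rep_$p < 0.001))

  same <- within(scores, {
    continuity <- logistics
    impressions <- logistics
  })
  rep0 <- compare_items_within(same)
  expect_true(all(rep0$degenerate))

  expect_error(compare_items_within(scores[1, ]), "fewer than 2")
})
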