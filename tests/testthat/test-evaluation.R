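test_that("call-name classification is keyword-driven and case-robust", {
  md <- data.frame(
    vocalization_id = c("v1", "v2", "v3", "v4", "v5"),
    call_name = c(
      "Duet.Song", "alarm bark", "Musical.Sequence",
      "  GREAT CALL ", "quaver interlude"
    ),
    context = c("pair duet", "", "display", "territorial display", NA),
    stringsAsFactors = FALSE
  )
  cl <- classify_call_names(md)
  expect_equal(cl$musical_flag, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(cl$matched_keyword[1], "song") # first match in keyword order
  expect_equal(cl$matched_keyword[3], "music")
  expect_true(all(cl$musical_flag == !is.na(cl$matched_keyword)))
  expect_equal(cl$context_category[2], "unlabeled")
  expect_equal(cl$context_category[5], "unlabeled")
})

test_that("index-label correlation has the right sign and matches rank arithmetic", {
  it <- data.frame(
    vocalization_id = sprintf("v%d", 1:6),
    ardi = c(3.2, 2.8, 2.5, 0.9, 0.4, 0.1), stringsAsFactors = FALSE
  )
  cl <- data.frame(
    vocalization_id = it$vocalization_id,
    musical_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  res <- index_label_correlation(it, cl)
  expect_gt(res$statistic, 0)
  # brute-force Pearson on midranks
  expect_equal(
    res$statistic,
    cor(rank(it$ardi), rank(as.numeric(cl$musical_flag)))
  )
  cl1 <- cl
  cl1$musical_flag <- TRUE
  expect_error(index_label_correlation(it, cl1), "both")
})

test_that("index-label correlation vanishes when labels are independent", {
  set.seed(31)
  it <- data.frame(
    vocalization_id = sprintf("v%d", 1:4000),
    ardi = runif(4000, 0, 5), stringsAsFactors = FALSE
  )
  cl <- data.frame(
    vocalization_id = it$vocalization_id,
    musical_flag = runif(4000) < 0.2, stringsAsFactors = FALSE
  )
  expect_lt(abs(index_label_correlation(it, cl)$statistic), 0.05)
})

test_that("rank-sum test reproduces hand enumerations", {
  r <- ranksum_test(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$statistic, 0) # U
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$method, "exact")
  r2 <- ranksum_test(c(5), c(1, 2, 3), alternative = "greater")
  expect_equal(r2$statistic, 3)
  expect_equal(r2$p_value, 1 / 4) # 1 of 4 arrangements as extreme
  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 3 * 3 / 2) # U = n1 n2 / 2 under symmetry
  expect_equal(same$statistic + same$U2, 9) # U + U' = n1 n2
})

test_that("rank-sum p values agree exactly with full permutation enumeration", {
  set.seed(32)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:6, 1)
    a <- sample(1:8, n1, replace = TRUE) # ties on purpose
    b <- sample(1:8, n2, replace = TRUE)
    for (alt in c("two.sided", "less", "greater")) {
      got <- ranksum_test(a, b, alternative = alt)
      expect_equal(got$p_value, oracle_ranksum(a, b, alt),
        tolerance = 1e-12,
        label = sprintf("seed case %d alt %s", i, alt)
      )
    }
  }
})

test_that("rank-sum statistic matches wilcox.test and large samples use the
           tie-corrected normal approximation", {
  set.seed(35)
  a <- rnorm(40)
  b <- rnorm(45, 0.5)
  got <- ranksum_test(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$method, "normal_tie_corrected")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Welch t handles the standard and degenerate cases", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$effect, -3)
  sw <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$effect, -r$effect)
  expect_equal(sw$p_value, r$p_value)
  flat <- welch_t_test(c(2, 2), c(5, 5))
  expect_match(flat$status, "undefined")
  expect_true(is.na(flat$p_value))
  both_flat <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(both_flat$statistic, 0)
  expect_equal(both_flat$p_value, 1)
})

test_that("Welch reduces to the pooled t for equal sizes and variances", {
  set.seed(36)
  a <- rnorm(20)
  b <- a * 1 + 2 # identical variance by construction
  w <- welch_t_test(a, b)
  p <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$df, 38, tolerance = 1e-9) # n1 + n2 - 2 in the limit
  expect_equal(w$statistic, unname(p$statistic), tolerance = 1e-9)
})

test_that("group-size categories follow the small-group definition", {
  expect_equal(categorize_group_size(4, FALSE), "small")
  expect_equal(categorize_group_size(20, FALSE), "large")
  expect_equal(categorize_group_size(1, TRUE), "solitary")
  expect_equal(categorize_group_size(NA, FALSE), "unknown")
  expect_equal(
    categorize_group_size(c(2, 6, 6.5, 10), c(FALSE, FALSE, FALSE, TRUE)),
    c("small", "small", "large", "solitary")
  )
})

test_that("the hypothesis battery recovers a built-in monogamy effect", {
  set.seed(37)
  n <- 60 # 30 species per arm
  ss <- data.frame(
    species = sprintf("S %d", 1:n),
    max_ardi = NA_real_,
    monogamous = rep(c(TRUE, FALSE), each = n / 2),
    wooded = sample(c(TRUE, FALSE), n, TRUE),
    arboreal = sample(c(TRUE, FALSE), n, TRUE),
    territorial = sample(c(TRUE, FALSE), n, TRUE),
    group_size = sample(c(2:6, 8:20), n, TRUE),
    solitary = FALSE,
    stringsAsFactors = FALSE
  )
  ss$max_ardi <- 1.5 + 1.2 * ss$monogamous + rnorm(n, 0, 0.6)
  hy <- run_hypothesis_battery(ss)
  mono <- hy[hy$test == "monogamous", ]
  expect_equal(mono$effect, 1.2, tolerance = 0.3)
  expect_true(all(!hy$adjusted))
  expect_true(all(is.na(hy$p_holm) | hy$p_holm >= hy$p_value))
  # single-class covariate is skipped with a notice
  ss2 <- ss
  ss2$wooded <- TRUE
  hy2 <- run_hypothesis_battery(ss2)
  expect_match(hy2$note[hy2$test == "wooded"], "skipped")
})

test_that("null covariates yield small statistics on average", {
  set.seed(38)
  stats <- replicate(20, {
    n <- 40
    ss <- data.frame(
      species = sprintf("S %d", 1:n),
      max_ardi = rnorm(n, 2, 1),
      monogamous = sample(c(TRUE, FALSE), n, TRUE),
      stringsAsFactors = FALSE
    )
    abs(run_hypothesis_battery(ss)$statistic)
  })
  expect_lt(mean(stats), 1.2)
})

test_that("rankings use min-rank ties and honor the subset filter", {
  it <- data.frame(
    vocalization_id = sprintf("v%d", 1:5),
    ardi = c(3, 2, 2, 1, 0.5), syllables = c(5, 4, 3, 2, 1),
    pc1_score = c(-3, -2, -1, 0, 1), log_sci = c(2, 2, 1.5, 1, 0.5),
    stringsAsFactors = FALSE
  )
  md <- data.frame(
    vocalization_id = it$vocalization_id,
    species = "A a", genus = "A",
    call_name = c("song", "duet", "trill song", "bark", "grunt"),
    stringsAsFactors = FALSE
  )
  rk <- ranking_table(it, md)
  expect_equal(rk$ardi_rank, c(1, 2, 2, 4, 5)) # tie then skip
  expect_equal(rk$pc1_rank, 1:5) # ascending orientation
  sub <- ranking_table(it, md, subset = c("song", "duet"))
  expect_equal(nrow(sub), 3)
  expect_equal(sub$ardi_rank, c(1, 2, 2))
  none <- ranking_table(it, md, subset = "chorus")
  expect_equal(nrow(none), 0)
})

test_that("context summaries match hand-computed category statistics", {
  it <- data.frame(
    vocalization_id = sprintf("v%d", 1:6),
    ardi = c(1, 2, 3, 4, 5, 6), syllables = 1:6, sci = rep(2, 6),
    stringsAsFactors = FALSE
  )
  cl <- data.frame(
    vocalization_id = it$vocalization_id,
    context_category = c("alarm", "alarm", "alarm", "display", "display", ""),
    stringsAsFactors = FALSE
  )
  cs <- context_summaries(it, cl)
  alarm <- cs[cs$context_category == "alarm" & cs$index == "ardi", ]
  expect_equal(alarm$n, 3)
  expect_equal(alarm$mean, 2)
  expect_equal(alarm$median, 2)
  disp <- cs[cs$context_category == "display" & cs$index == "ardi", ]
  expect_equal(disp$mean, 4.5)
  expect_true(disp$small_sample)
  expect_true("unlabeled" %in% cs$context_category)
})
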