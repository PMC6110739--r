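test_that("normality screen routes by sample size and agrees with its references", {
  set.seed(5)
  x <- rnorm(800)
  r <- test_normality(x)
  expect_identical(r$method, "shapiro_wilk")
  ref <- shapiro.test(x)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_true(r$is_normal)

  big <- rnorm(6000)
  rb <- test_normality(big)
  expect_identical(rb$method, "anderson_darling")
  expect_equal(rb$p_value, nortest::ad.test(big)$p.value)

  e <- rexp(200)
  expect_false(test_normality(e)$is_normal)

  expect_error(test_normality(c(1, 2)), class = "survmeta_insufficient_data")
  cv <- test_normality(rep(3, 50))
  expect_false(cv$is_normal)  # constant vector carries no evidence of normality
  expect_true(cv$degenerate)
})

test_that("test selection is a total deterministic map over the flow", {
  norm_yes <- structure(list(is_normal = TRUE), class = "normality_result")
  norm_no <- structure(list(is_normal = FALSE), class = "normality_result")
  cells <- list(
    list("continuous", 2L, norm_yes, "t_test"),
    list("continuous", 3L, norm_yes, "one_way_anova"),
    list("continuous", 2L, norm_no, "wilcoxon_rank_sum"),
    list("continuous", 3L, norm_no, "kruskal_wallis"),
    list("categorical", 2L, NULL, "chi_square"),
    list("categorical", 3L, NULL, "chi_square"),
    list("categorical", 2L, norm_yes, "chi_square"),
    list("categorical", 4L, norm_no, "chi_square")
  )
  for (cell in cells) {
    ch <- select_test(cell[[1]], cell[[2]], cell[[3]])
    expect_identical(ch$selected, cell[[4]])
    expect_true(length(ch$rationale) >= 3)
  }
  expect_error(select_test("continuous", 1L), class = "survmeta_test_error")
})

test_that("continuous comparisons run the selected reference test", {
  set.seed(9)
  x <- rnorm(120, 50, 8); g <- rep(0:1, 60)
  r <- compare_continuous(x, g)
  expect_identical(r$test$selected, "t_test")
  expect_equal(r$p_value, t.test(x ~ g)$p.value)
  expect_equal(r$group_summaries[["0"]]$mean, mean(x[g == 0]))
  expect_equal(r$group_summaries[["1"]]$max, max(x[g == 1]))

  # identical samples in both groups: statistic 0, p = 1 (normal scores keep
  # the parametric branch deterministic)
  xx <- rep(qnorm(ppoints(30)), 2); gg <- rep(0:1, each = 30)
  r0 <- compare_continuous(xx, gg)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)

  # three skewed groups route to Kruskal-Wallis
  y <- rexp(150); g3 <- rep(0:2, 50)
  r3 <- compare_continuous(y, g3)
  expect_identical(r3$test$selected, "kruskal_wallis")
  expect_equal(r3$p_value, kruskal.test(y, factor(g3))$p.value)

  # three normal groups route to one-way ANOVA
  z <- rnorm(150); r4 <- compare_continuous(z, g3)
  expect_identical(r4$test$selected, "one_way_anova")
  expect_equal(r4$p_value, oneway.test(z ~ factor(g3), var.equal = TRUE)$p.value)

  expect_error(compare_continuous(c(1, 2, 3), c(0, 0, 1)),
               class = "survmeta_degenerate_group")
})

test_that("a clear location shift is detected with high power", {
  set.seed(14)
  rej <- replicate(50, {
    x <- c(rnorm(100, 0), rnorm(100, 1))
    compare_continuous(x, rep(0:1, each = 100))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.99)
})

test_that("categorical comparisons use Pearson chi-square with Fisher fallback", {
  # balanced 2x2: independence by symmetry
  v <- rep(c(0, 1, 0, 1), each = 10)
  g <- rep(c(0, 0, 1, 1), each = 10)
  r <- compare_categorical(v, g)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  expect_false(r$fisher_fallback)

  # hand-computed Pearson value on [[20,5],[5,20]]
  v2 <- c(rep(0, 20), rep(1, 5), rep(0, 5), rep(1, 20))
  g2 <- rep(0:1, each = 25)
  r2 <- compare_categorical(v2, g2)
  O <- matrix(c(20, 5, 5, 20), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(unname(r2$statistic), sum((O - E)^2 / E))
  expect_equal(r2$p_value,
               pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))

  # sparse 2x2 triggers the exact test and flags it
  v3 <- c(rep(0, 8), rep(1, 2), rep(0, 3), rep(1, 7))
  g3 <- rep(0:1, each = 10)
  r3 <- compare_categorical(v3, g3)
  expect_true(r3$fisher_fallback)
  expect_identical(r3$test$selected, "fisher_exact")
  expect_equal(r3$p_value, fisher.test(table(v3, g3))$p.value)

  expect_error(compare_categorical(rep(1, 20), rep(0:1, 10)),
               class = "survmeta_test_error")
})

test_that("the demographic table separates sections, tests and flags", {
  set.seed(77)
  n <- 400
  strat <- rbinom(n, 1, 0.5)
  raw <- data.frame(
    time = round(rexp(n, 0.05), 3),
    status = strat,                                  # stratify by the event flag
    age = round(rnorm(n, 60, 10), 1),                # no shift across strata
    nodes = round(rnorm(n, 4 + 2.5 * strat, 2), 1),  # large shift
    sex = rbinom(n, 1, 0.5),
    allmiss = NA_character_,
    stringsAsFactors = FALSE
  )
  b <- generate_metadata(raw, overrides = list(allmiss = list(measurement = "ratio")))
  ds <- coded_dataset(raw, b)
  tab <- build_table1(ds, "status")
  expect_setequal(names(tab$continuous_rows), c("age", "nodes", "allmiss"))
  expect_setequal(names(tab$categorical_rows), c("sex"))
  expect_lt(tab$continuous_rows$nodes$p_value, 0.001)
  expect_gt(tab$continuous_rows$age$p_value, 0.01)
  expect_true(tab$continuous_rows$allmiss$untestable)
  # within-group percentages of a categorical block sum to 100
  for (gs in tab$categorical_rows$sex$group_summaries)
    expect_equal(sum(gs$percent), 100, tolerance = 1e-9)
  # group ns equal complete-case counts
  expect_identical(tab$categorical_rows$sex$n, sum(!is.na(raw$sex)))
  expect_error(build_table1(ds, "age"), class = "survmeta_stratifier_error")
})
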