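# Automatic baseline-characteristics ("Table 1") testing.
#
# The selection flow is sequential: data type (continuous vs categorical) ->
# number of strata -> normality -> method. Continuous variables are screened
# for normality per group (Shapiro-Wilk up to n = 5000, Anderson-Darling
# above); all groups normal routes to the parametric branch (Welch t-test for
# two groups, one-way ANOVA beyond), otherwise Wilcoxon rank-sum /
# Kruskal-Wallis. Categorical variables get Pearson chi-square without
# continuity correction, with a flagged Fisher exact fallback on 2x2 tables
# with any expected count below 5. All tests are two-sided and complete-case
# per variable.

#' Normality screen
#'
#' @param values numeric vector (NAs dropped).
#' @param method `"auto"` (Shapiro-Wilk for 3 <= n <= 5000, Anderson-Darling
#'   above), `"shapiro_wilk"` or `"anderson_darling"`.
#' @param alpha significance level of the screen (default 0.05).
#' @return object of class `normality_result`: `method`, `statistic`,
#'   `p_value`, `is_normal`, `n`.
#' @export
test_normality <- function(values, method = c("auto", "shapiro_wilk", "anderson_darling"),
                           alpha = 0.05) {
  method <- match.arg(method)
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L)
    stop_survmeta(paste0("normality test needs >= 3 values, got ", n),
                  "survmeta_insufficient_data")
  if (method == "auto")
    method <- if (n <= 5000L) "shapiro_wilk" else "anderson_darling"
  if (stats::sd(x) == 0) {
    # a constant vector carries no evidence of normality: route nonparametric
    return(structure(list(method = method, statistic = NA_real_,
                          p_value = NA_real_, is_normal = FALSE, n = n,
                          alpha = alpha, degenerate = TRUE),
                     class = "normality_result"))
  }
  ht <- if (method == "shapiro_wilk") {
    stats::shapiro.test(if (n > 5000L) sample(x, 5000L) else x)
  } else {
    nortest::ad.test(x)
  }
  structure(list(method = method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, is_normal = ht$p.value >= alpha,
                 n = n, alpha = alpha, degenerate = FALSE),
            class = "normality_result")
}

#' Select the comparison test
#'
#' Deterministic mapping of (analysis class, number of groups, normality):
#' continuous + 2 groups + normal -> t-test; continuous + >2 + normal ->
#' one-way ANOVA; continuous + 2 + non-normal -> Wilcoxon rank-sum;
#' continuous + >2 + non-normal -> Kruskal-Wallis; categorical -> chi-square
#' (Fisher exact fallback decided at comparison time on small 2x2 tables).
#'
#' @param spec a one-row layer-2 spec (or a string `"continuous"` /
#'   `"categorical"`).
#' @param n_groups number of strata (>= 2).
#' @param normality a `normality_result`, or `NULL` for categorical variables.
#' @return object of class `test_choice`: `variable`, `selected`, `rationale`
#'   (ordered trace of the decisions taken).
#' @export
select_test <- function(spec, n_groups, normality = NULL) {
  if (n_groups < 2L)
    stop_survmeta("no comparison possible with fewer than 2 groups",
                  "survmeta_test_error")
  if (is.character(spec)) {
    cls <- spec; variable <- NA_character_
  } else {
    cls <- spec$analysis_class; variable <- spec$name
  }
  trace <- c(paste0("data type: ", cls),
             paste0("strata: ", n_groups, " groups"))
  if (cls == "categorical") {
    selected <- "chi_square"
    trace <- c(trace, "categorical -> chi-square (Fisher exact fallback on sparse 2x2)")
  } else {
    normal <- !is.null(normality) && isTRUE(normality$is_normal)
    trace <- c(trace, paste0("normality: ", if (is.null(normality))
      "unavailable (treated as non-normal)" else if (normal) "normal" else "non-normal"))
    selected <- if (normal) {
      if (n_groups == 2L) "t_test" else "one_way_anova"
    } else {
      if (n_groups == 2L) "wilcoxon_rank_sum" else "kruskal_wallis"
    }
    trace <- c(trace, paste0("selected: ", selected))
  }
  structure(list(variable = variable, selected = selected, rationale = trace),
            class = "test_choice")
}

group_summaries <- function(values, group) {
  lv <- sort(unique(group))
  out <- lapply(lv, function(g) {
    x <- values[group == g]
    list(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
         min = min(x), max = max(x))
  })
  names(out) <- as.character(lv)
  out
}

#' Compare a continuous variable across groups
#'
#' Complete cases only. Normality is screened per group; the parametric branch
#' requires every group to pass. Welch t-test by default for two groups
#' (`var_equal = TRUE` pools variances), classical one-way ANOVA beyond.
#'
#' @param values numeric vector.
#' @param group grouping codes (same length).
#' @param alpha_normality significance level of the normality screen.
#' @param var_equal pool variances in the two-group t-test.
#' @param normality_method passed to [test_normality()].
#' @return object of class `comparison_result`: `test` (a `test_choice`),
#'   `statistic`, `df`, `p_value`, `group_summaries`, `n`.
#' @export
compare_continuous <- function(values, group, alpha_normality = 0.05,
                               var_equal = FALSE, normality_method = "auto") {
  cc <- !is.na(values) & !is.na(group)
  x <- values[cc]; g <- group[cc]
  lv <- sort(unique(g))
  if (length(lv) < 2L)
    stop_survmeta("fewer than 2 non-empty groups after complete-case reduction",
                  "survmeta_test_error")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop_survmeta(paste0("group '", names(sizes)[sizes < 2L][1L],
                         "' has fewer than 2 complete cases"),
                  "survmeta_degenerate_group")
  per_group_normal <- vapply(lv, function(l) {
    xi <- x[g == l]
    if (length(xi) < 3L) return(FALSE)  # too small to certify: nonparametric
    tryCatch(test_normality(xi, method = normality_method,
                            alpha = alpha_normality)$is_normal,
             survmeta_error = function(e) FALSE)
  }, logical(1))
  norm <- structure(list(method = normality_method, statistic = NA_real_,
                         p_value = NA_real_, is_normal = all(per_group_normal),
                         n = length(x), alpha = alpha_normality,
                         degenerate = FALSE),
                    class = "normality_result")
  choice <- select_test("continuous", length(lv), norm)
  ht <- switch(choice$selected,
    t_test = stats::t.test(x ~ factor(g), var.equal = var_equal),
    one_way_anova = stats::oneway.test(x ~ factor(g), var.equal = TRUE),
    wilcoxon_rank_sum = stats::wilcox.test(x ~ factor(g), exact = FALSE, correct = FALSE),
    kruskal_wallis = stats::kruskal.test(x, factor(g)))
  df <- if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_
  structure(list(test = choice, statistic = unname(ht$statistic), df = df,
                 p_value = ht$p.value, group_summaries = group_summaries(x, g),
                 n = length(x)),
            class = "comparison_result")
}

#' Compare a categorical variable across groups
#'
#' Pearson chi-square without continuity correction on the contingency table
#' of complete cases; on a 2x2 table with any expected count below 5 the
#' Fisher exact test is used instead and flagged in the result.
#'
#' @param values categorical codes.
#' @param group grouping codes (same length).
#' @return a `comparison_result`; `fisher_fallback` records whether the exact
#'   test replaced the chi-square.
#' @export
compare_categorical <- function(values, group) {
  cc <- !is.na(values) & !is.na(group)
  x <- values[cc]; g <- group[cc]
  tab <- table(factor(x), factor(g))
  tab <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_survmeta("a factor collapses to one level: comparison impossible",
                  "survmeta_test_error")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fisher <- nrow(tab) == 2L && ncol(tab) == 2L && any(expected < 5)
  choice <- select_test("categorical", ncol(tab))
  if (fisher) {
    ht <- stats::fisher.test(tab)
    choice$selected <- "fisher_exact"
    choice$rationale <- c(choice$rationale,
                          "2x2 with expected count < 5 -> Fisher exact")
    stat <- NA_real_; df <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic); df <- unname(ht$parameter)
  }
  counts <- lapply(colnames(tab), function(cg) {
    cnt <- tab[, cg]
    list(group = cg, n = sum(cnt), counts = as.integer(cnt),
         levels = rownames(tab), percent = 100 * as.numeric(cnt) / sum(cnt))
  })
  names(counts) <- colnames(tab)
  structure(list(test = choice, statistic = stat, df = df, p_value = ht$p.value,
                 group_summaries = counts, n = length(x),
                 fisher_fallback = fisher, table = tab),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test$selected, ": statistic = ",
      if (is.na(x$statistic)) "-" else format(x$statistic, digits = 4),
      ", p = ", format.pval(x$p_value, digits = 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Build the stratified baseline-characteristics table
#'
#' Every layer-2 covariate is summarised per stratum and tested with the
#' automatically selected method. Continuous rows carry mean, sd, min, max and
#' n per group; categorical rows carry per-level counts and within-group
#' percentages. A covariate that cannot be tested (e.g. fully missing) is kept
#' in the table and flagged, never silently dropped.
#'
#' @param ds a `coded_dataset`.
#' @param strat stratifying column (must be categorical with >= 2 observed
#'   levels).
#' @param bundle metadata bundle; defaults to the one embedded in `ds`.
#' @param alpha_normality normality-screen level for continuous covariates.
#' @return object of class `demographic_table`.
#' @export
build_table1 <- function(ds, strat, bundle = ds$bundle, alpha_normality = 0.05) {
  l2 <- bundle$layer2
  if (!strat %in% l2$name)
    stop_survmeta(paste0("unknown stratifier '", strat, "'"), "survmeta_input_error")
  if (l2$analysis_class[l2$name == strat] != "categorical")
    stop_survmeta(paste0("stratifier '", strat, "' must be categorical"),
                  "survmeta_stratifier_error")
  gv <- ds$data[[strat]]
  if (length(unique(gv[!is.na(gv)])) < 2L)
    stop_survmeta("stratifier has fewer than 2 observed levels",
                  "survmeta_stratifier_error")
  covs <- l2$name[l2$role %in% c("covariate") & l2$name != strat]
  continuous_rows <- list(); categorical_rows <- list()
  for (v in covs) {
    x <- ds$data[[v]]
    cls <- l2$analysis_class[l2$name == v]
    res <- tryCatch({
      if (cls == "continuous")
        compare_continuous(x, gv, alpha_normality = alpha_normality)
      else
        compare_categorical(x, gv)
    }, survmeta_error = function(e)
      structure(list(test = NULL, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, group_summaries = NULL,
                     n = sum(!is.na(x) & !is.na(gv)),
                     untestable = TRUE, reason = conditionMessage(e)),
                class = "comparison_result"))
    if (cls == "continuous") continuous_rows[[v]] <- res
    else categorical_rows[[v]] <- res
  }
  structure(list(strat_variable = strat,
                 strat_levels = sort(unique(gv[!is.na(gv)])),
                 continuous_rows = continuous_rows,
                 categorical_rows = categorical_rows,
                 n_per_group = table(gv)),
            class = "demographic_table")
}

#' @export
print.demographic_table <- function(x, ...) {
  cat("Demographic table stratified by", x$strat_variable, "\n")
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$n_per_group),
                                      as.integer(x$n_per_group)), collapse = ", "), "\n")
  show <- function(rows, label) {
    if (length(rows) == 0L) return(invisible())
    cat(" ", label, "\n")
    for (v in names(rows)) {
      r <- rows[[v]]
      if (isTRUE(r$untestable)) {
        cat(sprintf("    %-12s untestable (%s)\n", v, r$reason))
      } else {
        cat(sprintf("    %-12s %-18s p = %s\n", v, r$test$selected,
                    format.pval(r$p_value, digits = 3)))
      }
    }
  }
  show(x$continuous_rows, "continuous")
  show(x$categorical_rows, "categorical")
  invisible(x)
}
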