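test_that("product-limit estimate reproduces hand-evaluated risk-set products", {
  # no censoring: survival is the empirical fraction still alive
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$conditional_prob, c(2 / 3, 1 / 2, 0))
  expect_equal(km$n_at_risk, c(3, 2, 1))

  # censoring at t=2 removes the subject from later risk sets: risk sets 3, 1
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$event_times, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km2$n_at_risk, c(3, 1))

  # all censored: constant at 1, with a warning
  expect_warning(km0 <- km_estimate(c(1, 2), c(0, 0)),
                 class = "survmeta_all_censored")
  expect_length(km0$event_times, 0)
  expect_equal(km_survival_at(km0, c(0.5, 5)), c(1, 1))
})

test_that("the survival curve is a running product of conditional probabilities", {
  set.seed(3)
  time <- rexp(80); event <- rbinom(80, 1, 0.7)
  km <- km_estimate(time, event)
  expect_equal(km$survival, cumprod(km$conditional_prob))
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_true(all(diff(km$n_at_risk) < 0))
})

test_that("without censoring the KM curve is 1 - ECDF and Greenwood closes", {
  set.seed(8)
  time <- round(rexp(60), 2)  # some ties
  km <- km_estimate(time, rep(1, 60))
  n <- 60
  for (i in seq_along(km$event_times)) {
    s_emp <- mean(time > km$event_times[i])
    expect_equal(km$survival[i], s_emp)
    expect_equal(km$greenwood_var[i], s_emp * (1 - s_emp) / n)
  }
})

test_that("KM matches the reference implementation on censored data", {
  skip_if_not_installed("survival")
  set.seed(21)
  time <- round(rexp(150, 0.2), 1); event <- rbinom(150, 1, 0.6)
  km <- km_estimate(time, event)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                  conf.type = "log-log"),
                times = km$event_times)
  expect_equal(km$survival, sf$surv)
  # at S = 0 the reference reports NaN/NA where this package uses the
  # degenerate limit 0; compare where the estimate is positive
  pos <- km$survival > 0
  expect_equal(sqrt(km$greenwood_var)[pos], sf$std.err[pos], tolerance = 1e-12)
  expect_equal(km$ci_lower[pos], sf$lower[pos])
  expect_equal(km$ci_upper[pos], sf$upper[pos])
})

test_that("median survival uses the first crossing of 0.5", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(median_survival(km)$median, 2)
  expect_warning(km1 <- km_estimate(c(1, 2), c(0, 0)), class = "survmeta_all_censored")
  expect_false(median_survival(km1)$reached)
  # exactly 0.5 counts as reached (<= convention)
  km5 <- km_estimate(c(5, 5, 6, 6), c(1, 1, 0, 0))
  expect_equal(km5$survival, 0.5)
  expect_equal(median_survival(km5)$median, 5)
})

test_that("two-group log-rank equals direct hypergeometric summation", {
  # identical groups: O - E = 0, statistic 0, p = 1
  t0 <- c(1, 2, 4, 1, 2, 4); e0 <- c(1, 0, 1, 1, 0, 1); g0 <- rep(0:1, each = 3)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(unname(lr0$observed - lr0$expected), c(0, 0))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  # 4-subject fixture: every quantity from the by-hand accumulation
  t1 <- c(1, 2, 3, 4); e1 <- rep(1, 4); g1 <- c(0, 0, 1, 1)
  lr <- logrank_test(t1, e1, g1)
  hand <- logrank_by_hand(t1, e1, g1)
  expect_equal(unname(lr$observed), unname(hand$O))
  expect_equal(unname(lr$expected), unname(hand$E))
  expect_equal(lr$variance[2, 2], hand$V2)
  expect_equal(lr$statistic, unname(hand$stat))
  expect_identical(lr$df, 1L)
  expect_equal(sum(lr$observed - lr$expected), 0)
})

test_that("multi-group and stratified log-rank match the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(31)
  n <- 240
  time <- round(rexp(n, 0.1), 1); event <- rbinom(n, 1, 0.7)
  g <- sample(0:2, n, TRUE); st <- sample(0:1, n, TRUE)
  lr3 <- logrank_test(time, event, g)
  sd3 <- survival::survdiff(survival::Surv(time, event) ~ g)
  expect_equal(lr3$statistic, sd3$chisq)
  expect_equal(unname(lr3$expected), unname(sd3$exp))
  expect_identical(lr3$df, 2L)
  lrs <- logrank_test(time, event, g, strata = st)
  sds <- survival::survdiff(survival::Surv(time, event) ~ g +
                              survival::strata(st))
  expect_equal(lrs$statistic, sds$chisq)
})

test_that("Cox partial likelihood is maximized where symmetry says it must be", {
  # both arms share the event pattern: beta-hat = 0
  fit <- fit_coxph(c(1, 3, 1, 3), c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("Cox estimate matches brute-force grid maximization (n = 15, no ties)", {
  set.seed(45)
  n <- 15
  x <- rbinom(n, 1, 0.5)
  time <- sort(rexp(n, 0.1 * exp(0.8 * x)))  # distinct almost surely
  event <- rbinom(n, 1, 0.8); event[1] <- 1
  stopifnot(!anyDuplicated(time))
  fit <- fit_coxph(time, event, x, ties = "efron")
  bhat <- cox_grid_oracle(time, event, x)
  expect_equal(unname(coef(fit)), bhat, tolerance = 1e-4)
  # without ties Efron and Breslow coincide
  expect_equal(coef(fit_coxph(time, event, x, ties = "breslow")), coef(fit))
})

test_that("the score test at beta = 0 is the log-rank statistic (Breslow, no ties)", {
  set.seed(52)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.5 * x))
  event <- rbinom(n, 1, 0.8); event[1] <- 1
  fit <- fit_coxph(time, event, x, ties = "breslow")
  lr <- logrank_test(time, event, x)
  expect_equal(fit$score_at_zero, lr$statistic, tolerance = 1e-8)
})

test_that("Cox fit agrees with the reference implementation under ties and strata", {
  skip_if_not_installed("survival")
  set.seed(60)
  n <- 250
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  time <- round(rexp(n, 0.1 * exp(0.6 * x - 0.4 * z)), 1)
  time[time == 0] <- 0.1
  event <- rbinom(n, 1, 0.7)
  st <- sample(0:1, n, TRUE)
  for (ti in c("efron", "breslow")) {
    f1 <- fit_coxph(time, event, cbind(x = x, z = z), strata = st, ties = ti)
    f2 <- survival::coxph(survival::Surv(time, event) ~ x + z +
                            survival::strata(st), ties = ti)
    expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
    expect_equal(unname(f1$standard_errors), unname(sqrt(diag(vcov(f2)))),
                 tolerance = 1e-7)
    expect_equal(f1$log_likelihood, f2$loglik[2], tolerance = 1e-9)
  }
})

test_that("the partial likelihood never decreases across Newton-Raphson iterations", {
  set.seed(71)
  for (r in 1:5) {
    n <- 120
    x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
    time <- rexp(n, 0.1 * exp(0.5 * x[, 1]))
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    fit <- fit_coxph(time, event, x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    expect_equal(fit$hazard_ratios, exp(fit$coefficients))
    expect_true(all(fit$hr_lower < fit$hazard_ratios &
                    fit$hazard_ratios < fit$hr_upper))
  }
})

test_that("degenerate Cox inputs are rejected with named diagnostics", {
  expect_error(fit_coxph(c(1, 2, 3, 4), c(1, 1, 1, 1), rep(2, 4)),
               class = "survmeta_identifiability_error")
  expect_error(fit_coxph(c(1, 2, 3), c(0, 0, 0), c(0, 1, 0)),
               class = "survmeta_input_error")
  # complete separation: covariate perfectly orders the failures
  xs <- c(rep(1, 10), rep(0, 10))
  ts <- c(1:10, 11:20)
  expect_error(fit_coxph(ts, rep(1, 20), xs),
               class = "survmeta_separation_error")
})

test_that("time rescaling leaves the rank-based estimates unchanged", {
  set.seed(83)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.4 * x)); event <- rbinom(n, 1, 0.7)
  f1 <- fit_coxph(time, event, x)
  f2 <- fit_coxph(time * 7.3, event, x)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(logrank_test(time, event, x)$statistic,
               logrank_test(time * 7.3, event, x)$statistic)
  expect_equal(km_estimate(time, event)$survival,
               km_estimate(time * 7.3, event)$survival)
})

test_that("formula interface expands covariate level combinations into curves", {
  set.seed(90)
  res <- simulate_cohort(colon_like_spec(n = 300, seed = 4))
  ds <- coded_dataset(res$dataset, sim_bundle(res$truth))

  one <- km_by_formula(ds, survival_formula("TimeOS", "EventDeath", "rx"))
  expect_length(one$curves, 2)
  expect_identical(one$logrank$df, 1L)

  two <- km_by_formula(ds, survival_formula("TimeOS", "EventDeath",
                                            c("rx", "sex")))
  expect_length(two$curves, 4)
  expect_identical(two$logrank$df, 3L)

  # a numeric covariate expands over its unique values
  ds$data$grade3 <- sample(1:3, ds$n_rows, TRUE)
  ds$bundle$layer2 <- rbind(ds$bundle$layer2,
                            layer2_specs("grade3", "nominal", "covariate"))
  three <- km_by_formula(ds, survival_formula("TimeOS", "EventDeath", "grade3"))
  expect_length(three$curves, 3)

  ds$data$idnum <- seq_len(ds$n_rows)
  ds$bundle$layer2 <- rbind(ds$bundle$layer2,
                            layer2_specs("idnum", "ratio", "covariate"))
  expect_error(km_by_formula(ds, survival_formula("TimeOS", "EventDeath", "idnum")),
               class = "survmeta_group_explosion")

  # endpoint level recodes the event on the fly
  alt <- km_by_formula(ds, survival_formula("TimeOS", "EventDeath", "rx",
                                            endpoint_level = 0L))
  expect_identical(alt$curves[[1]]$n_events_total,
                   as.integer(sum(ds$data$EventDeath[ds$data$rx == 0] == 0)))

  fit <- coxph_by_formula(ds, survival_formula("TimeOS", "EventDeath",
                                               c("rx", "age"), strata = "sex"))
  expect_named(coef(fit), c("rx", "age"))
})
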