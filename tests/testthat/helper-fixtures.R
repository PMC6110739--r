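# Shared in-code fixtures: a toy trial table and its metadata bundle.

toy_bundle <- function() {
  metadata_bundle(
    layer1_roles("OS_months", "status",
                 extend_columns = c(OS_months = "TimeOS", status = "EventDeath")),
    layer2_specs(c("TimeOS", "EventDeath", "age", "sex", "extent"),
                 c("ratio", "nominal", "ratio", "nominal", "ordinal"),
                 c("time", "event", "covariate", "covariate", "covariate")),
    layer3_map(c("EventDeath", "EventDeath", "sex", "sex",
                 "extent", "extent", "extent"),
               c(0L, 1L, 0L, 1L, 1L, 2L, 3L),
               c("0|alive", "1|dead", "0|f|F", "1|m|M", "1", "2", "3"),
               c("alive", "dead", "female", "male",
                 "submucosa", "muscle", "serosa"))
  )
}

toy_raw <- function() {
  data.frame(
    OS_months = c("12", "5.5", "30", "2", "18", "7", "25", "14", "9", "40"),
    status = c("dead", "1", "0", "alive", "1", "dead", "0", "1", "alive", "0"),
    age = c("61", "70", "", "55", "49", "80", "66", "58", "72", "45"),
    sex = c("M", "f", "1", "0", "m", "F", "M", "f", "1", "0"),
    extent = c("3", "2", "3", "1", "2", "3", "3", "2", "1", "3"),
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function() coded_dataset(toy_raw(), toy_bundle())

# random raw tables for property-style metadata/etl checks
random_raw_table <- function(n = 30L) {
  data.frame(
    time = round(stats::rexp(n, 0.1), 3),
    event = stats::rbinom(n, 1L, 0.6),
    cont = round(stats::rnorm(n, 50, 10), 2),
    cat3 = sample(0:2, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# independent brute-force log-rank accumulation used as oracle
logrank_by_hand <- function(time, event, group) {
  lv <- sort(unique(group))
  O <- E <- stats::setNames(numeric(length(lv)), lv)
  V <- 0
  for (u in sort(unique(time[event == 1]))) {
    risk <- time >= u
    n <- sum(risk); d <- sum(event == 1 & time == u)
    for (i in seq_along(lv)) {
      ng <- sum(risk & group == lv[i])
      dg <- sum(event == 1 & time == u & group == lv[i])
      O[i] <- O[i] + dg
      E[i] <- E[i] + d * ng / n
    }
    ng2 <- sum(risk & group == lv[2])
    if (n > 1) V <- V + d * (n - d) / (n - 1) * ng2 * (n - ng2) / n^2
  }
  list(O = O, E = E, V2 = V, stat = (O[2] - E[2])^2 / V)
}

# independent grid maximizer of the one-covariate partial likelihood (no ties)
cox_grid_oracle <- function(time, event, x, lower = -3, upper = 3) {
  pl <- function(beta) {
    vapply(beta, function(b) {
      ll <- 0
      for (i in which(event == 1)) {
        risk <- which(time >= time[i])
        ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
      }
      ll
    }, numeric(1))
  }
  coarse <- seq(lower, upper, by = 1e-3)
  b0 <- coarse[which.max(pl(coarse))]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-5)
  fine[which.max(pl(fine))]
}
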