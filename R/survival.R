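# Right-censored survival core: product-limit estimator with Greenwood
# variance, the (stratified, multi-group) log-rank test, and Cox proportional
# hazards fitted by Newton-Raphson on the partial likelihood with Efron or
# Breslow handling of tied event times. All three are implemented here
# directly; nothing is delegated.
#
# Conventions: event = 1 marks death/event, 0 right censoring; subjects
# censored at time t remain in the risk set for events at t.

check_sample <- function(time, event, group = NULL, strata = NULL) {
  if (length(time) != length(event))
    stop_survmeta("time and event lengths differ", "survmeta_input_error")
  if (!is.null(group) && length(group) != length(time))
    stop_survmeta("group length differs from time", "survmeta_input_error")
  if (!is.null(strata) && length(strata) != length(time))
    stop_survmeta("strata length differs from time", "survmeta_input_error")
  if (any(!is.finite(time)) || any(time < 0))
    stop_survmeta("times must be finite and nonnegative", "survmeta_input_error")
  if (!all(event %in% c(0, 1)))
    stop_survmeta("event must be 0 (censored) or 1 (event)", "survmeta_input_error")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimator
#'
#' The survival function is the running product of the per-event-time
#' conditional survival fractions: at each distinct time with d events out of
#' n at risk, S(t) = S(t-) * (1 - d/n). Variance by Greenwood's formula,
#' pointwise confidence band on the log(-log) scale by default (a plain linear
#' Greenwood band is available).
#'
#' @param time nonnegative observed times.
#' @param event 0/1 event flags (1 = event).
#' @param group optional grouping codes; one curve is returned per group.
#' @param conf_level confidence level of the pointwise band (default 0.95).
#' @param conf_type `"log-log"` (default, keeps the band inside `[0,1]`) or
#'   `"plain"`.
#' @return a `km_curve` (or a named `km_curve_list`, one per group) with
#'   `event_times`, `n_at_risk`, `n_events`, `n_censored`, `conditional_prob`,
#'   `survival`, `greenwood_var`, `ci_lower`, `ci_upper`.
#' @export
km_estimate <- function(time, event, group = NULL, conf_level = 0.95,
                        conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  check_sample(time, event, group)
  if (!is.null(group)) {
    lv <- sort(unique(group[!is.na(group)]))
    curves <- lapply(lv, function(g)
      km_one(time[group == g & !is.na(group)], event[group == g & !is.na(group)],
             conf_level, conf_type, label = as.character(g)))
    names(curves) <- as.character(lv)
    return(structure(curves, class = "km_curve_list"))
  }
  km_one(time, event, conf_level, conf_type)
}

km_one <- function(time, event, conf_level, conf_type, label = NULL) {
  n <- length(time)
  if (n < 1L)
    stop_survmeta("empty sample", "survmeta_input_error")
  if (sum(event) == 0L)
    warn_survmeta("no events observed: survival curve is constant at 1",
                  "survmeta_all_censored")
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]
  ut <- unique(t_s)
  d_at <- vapply(ut, function(u) sum(d_s[t_s == u]), numeric(1))
  c_at <- vapply(ut, function(u) sum(t_s == u) - sum(d_s[t_s == u]), numeric(1))
  nrisk_all <- n - c(0, cumsum(d_at + c_at))[seq_along(ut)]
  keep <- d_at > 0
  et <- ut[keep]; d <- d_at[keep]; nr <- nrisk_all[keep]
  cond <- 1 - d / nr                       # conditional survival past each event time
  surv <- cumprod(cond)
  gw_terms <- d / (nr * (nr - d))
  gw_terms[nr == d] <- NA_real_            # S hits 0: Greenwood undefined there
  greenwood_var <- surv^2 * cumsum(ifelse(is.na(gw_terms), 0, gw_terms))
  greenwood_var[surv == 0] <- 0   # degenerate limit of S^2 * sum(...) as S -> 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain") {
    se <- sqrt(greenwood_var)
    lo <- pmax(surv - z * se, 0); hi <- pmin(surv + z * se, 1)
  } else {
    # var of log(-log S) by the delta method
    vloglog <- greenwood_var / (surv * log(surv))^2
    ok <- is.finite(vloglog) & surv > 0 & surv < 1
    lo <- hi <- rep(NA_real_, length(surv))
    lo[ok] <- surv[ok]^exp(z * sqrt(vloglog[ok]))
    hi[ok] <- surv[ok]^exp(-z * sqrt(vloglog[ok]))
    lo[surv == 0] <- 0; hi[surv == 0] <- 0
    lo[surv == 1] <- hi[surv == 1] <- 1
  }
  structure(list(event_times = et, n_at_risk = nr, n_events = d,
                 conditional_prob = cond, survival = surv,
                 greenwood_var = greenwood_var,
                 ci_lower = lo, ci_upper = hi,
                 conf_level = conf_level, conf_type = conf_type,
                 n = n, n_events_total = sum(event),
                 censor_times = time[event == 0], label = label),
            class = "km_curve")
}

#' Survival estimate at arbitrary times
#'
#' Right-continuous step evaluation of a fitted curve.
#'
#' @param curve a `km_curve`.
#' @param times evaluation times.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(tt) {
    k <- sum(curve$event_times <= tt)
    if (k == 0L) 1 else curve$survival[k]
  }, numeric(1))
}

#' Median survival time
#'
#' Smallest event time at which the survival estimate drops to 0.5 or below;
#' `NA` with `reached = FALSE` when the curve never reaches 0.5.
#'
#' @param curve a `km_curve`.
#' @return list with `median` (time or `NA`) and `reached`.
#' @export
median_survival <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0L) list(median = NA_real_, reached = FALSE)
  else list(median = curve$event_times[min(idx)], reached = TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_survival(x)
  cat("Kaplan-Meier curve", if (!is.null(x$label)) paste0("[", x$label, "]") else "",
      "\n  n =", x$n, ", events =", x$n_events_total,
      ", median =", if (med$reached) format(med$median) else "not reached", "\n")
  invisible(x)
}

#' @export
print.km_curve_list <- function(x, ...) {
  for (cv in x) print(cv)
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  data.frame(time = object$event_times, n_risk = object$n_at_risk,
             n_event = object$n_events, survival = object$survival,
             std_err = sqrt(object$greenwood_var),
             ci_lower = object$ci_lower, ci_upper = object$ci_upper)
}

#' Log-rank test
#'
#' Observed minus expected event counts accumulated over distinct event
#' times; at each time the group event counts are hypergeometric given the
#' margins, giving expectation d*n_g/n and covariance
#' d (n-d)/(n-1) * (n_g/n)(delta_gh - n_h/n). The two-group statistic is
#' (O2-E2)^2 / Var(O2-E2); k groups use the vector/matrix generalization with
#' k-1 degrees of freedom. With strata, O-E and the covariance are summed over
#' strata before the statistic is formed. Risk sets of size 1 contribute zero
#' variance.
#'
#' @param time,event the survival sample.
#' @param group group codes (>= 2 groups).
#' @param strata optional stratum codes (per-stratum risk sets).
#' @return object of class `logrank_result`: `observed`, `expected`,
#'   `variance` (k x k), `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group, strata = NULL) {
  check_sample(time, event, group, strata)
  cc <- !is.na(time) & !is.na(event) & !is.na(group) &
    (if (is.null(strata)) TRUE else !is.na(strata))
  time <- time[cc]; event <- event[cc]; group <- group[cc]
  strata <- if (is.null(strata)) rep(1L, length(time)) else strata[cc]
  lv <- sort(unique(group))
  k <- length(lv)
  if (k < 2L)
    stop_survmeta("log-rank needs >= 2 groups", "survmeta_test_error")
  if (sum(event) == 0L)
    stop_survmeta("log-rank needs >= 1 event", "survmeta_test_error")
  O <- E <- stats::setNames(numeric(k), as.character(lv))
  V <- matrix(0, k, k, dimnames = list(lv, lv))
  for (s in unique(strata)) {
    inS <- strata == s
    ts <- time[inS]; ds <- event[inS]; gs <- group[inS]
    for (u in sort(unique(ts[ds == 1]))) {
      at_risk <- ts >= u
      n_u <- sum(at_risk)
      d_u <- sum(ds == 1 & ts == u)
      n_g <- vapply(lv, function(l) sum(at_risk & gs == l), numeric(1))
      d_g <- vapply(lv, function(l) sum(ds == 1 & ts == u & gs == l), numeric(1))
      O <- O + d_g
      E <- E + d_u * n_g / n_u
      if (n_u > 1L) {
        f <- d_u * (n_u - d_u) / (n_u - 1)
        p <- n_g / n_u
        V <- V + f * (diag(p, nrow = k) - outer(p, p))
      }
    }
  }
  OmE <- O - E
  idx <- seq_len(k - 1L)
  Vr <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    drop(t(OmE[idx]) %*% solve(Vr, OmE[idx])),
    error = function(e) {
      # singular covariance (e.g. empty interior groups): pseudo-inverse
      sv <- svd(Vr)
      pos <- sv$d > max(sv$d) * 1e-12
      ginv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      drop(t(OmE[idx]) %*% ginv %*% OmE[idx])
    })
  stat <- max(stat, 0)
  df <- k - 1L
  structure(list(observed = O, expected = E, variance = V,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n = length(time), groups = lv,
                 stratified = length(unique(strata)) > 1L),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test", if (x$stratified) "(stratified)" else "", "\n")
  tab <- data.frame(group = names(x$observed), observed = x$observed,
                    expected = round(x$expected, 2), row.names = NULL)
  print(tab)
  cat(sprintf("  chi-square = %.4f on %d df, p = %s\n", x$statistic, x$df,
              format.pval(x$p_value, digits = 4)))
  invisible(x)
}

# partial log-likelihood, score and observed information at beta, summed over
# strata; the Efron correction replaces the Breslow denominator at a tied
# event time by d averaged denominators with the tied deaths progressively
# downweighted
cox_pl <- function(beta, time, event, X, strata, ties) {
  p <- ncol(X)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (s in unique(strata)) {
    inS <- which(strata == s)
    ord <- inS[order(time[inS])]
    t_s <- time[ord]; d_s <- event[ord]; Xs <- X[ord, , drop = FALSE]
    eta <- drop(Xs %*% beta)
    eta <- eta - max(eta)                # guard against overflow; cancels in ratios
    w <- exp(eta)
    first <- which(!duplicated(t_s))     # index of first subject at each distinct time
    ut <- t_s[first]
    # risk-set sums: revcumsum evaluated at the first index of each time
    S0r <- revcumsum(w)
    S1r <- apply(Xs * w, 2, revcumsum)
    if (p == 1L) S1r <- matrix(S1r, ncol = 1L)
    # S2 as revcumsums of the p(p+1)/2 upper-triangle products
    pair_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    S2r <- sapply(seq_len(nrow(pair_idx)), function(m)
      revcumsum(w * Xs[, pair_idx[m, 1]] * Xs[, pair_idx[m, 2]]))
    if (!is.matrix(S2r)) S2r <- matrix(S2r, ncol = nrow(pair_idx))
    for (j in seq_along(ut)) {
      u <- ut[j]
      D <- which(t_s == u & d_s == 1)
      d <- length(D)
      if (d == 0L) next
      fi <- first[j]
      S0 <- S0r[fi]
      S1 <- S1r[fi, ]
      S2 <- matrix(0, p, p)
      for (m in seq_len(nrow(pair_idx))) {
        a <- pair_idx[m, 1]; b <- pair_idx[m, 2]
        S2[a, b] <- S2[b, a] <- S2r[fi, m]
      }
      wD <- w[D]
      XD <- Xs[D, , drop = FALSE]
      sd0 <- sum(wD)
      sd1 <- drop(crossprod(XD, wD))
      sd2 <- crossprod(XD * sqrt(wD))
      ll <- ll + sum(eta[D])
      U <- U + colSums(XD)
      fracs <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
      for (f in fracs) {
        M0 <- S0 - f * sd0
        M1 <- S1 - f * sd1
        M2 <- S2 - f * sd2
        ll <- ll - log(M0)
        U <- U - M1 / M0
        I <- I + M2 / M0 - tcrossprod(M1 / M0) / 1
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with step halving,
#' starting from beta = 0, until the score sup-norm falls below `tol` or the
#' relative log-likelihood change does. Tied event times are handled by the
#' Efron correction (default) or Breslow. Strata get separate risk sets (one
#' baseline hazard per stratum). Standard errors come from the inverse of the
#' observed information at the optimum; hazard ratios are exp(beta) with Wald
#' confidence intervals. Missing values are eliminated (complete cases) before
#' fitting.
#'
#' @param time,event the survival sample.
#' @param X covariate matrix (or data frame / vector), one column per term.
#' @param strata optional stratum codes.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the score sup-norm (default 1e-9).
#' @param max_iter Newton-Raphson iteration cap (default 50).
#' @param conf_level Wald CI level for hazard ratios.
#' @return object of class `cox_model`: `coefficients`, `standard_errors`,
#'   `hazard_ratios` (with `hr_lower`/`hr_upper`), `log_likelihood` (value at
#'   convergence), `loglik_trace`, `null_loglik`, `score_at_zero` (score test
#'   statistic at beta = 0), `iterations`, `converged`, `ties_method`,
#'   `strata_levels`, `vcov`, `n`, `n_events`.
#' @export
fit_coxph <- function(time, event, X, strata = NULL, ties = c("efron", "breslow"),
                      tol = 1e-9, max_iter = 50L, conf_level = 0.95) {
  ties <- match.arg(ties)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L, dimnames = list(NULL, "x"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_sample(time, event, strata = strata)
  cc <- !is.na(time) & !is.na(event) & stats::complete.cases(X) &
    (if (is.null(strata)) TRUE else !is.na(strata))
  time <- time[cc]; event <- event[cc]; X <- X[cc, , drop = FALSE]
  strata <- if (is.null(strata)) rep(1L, length(time)) else strata[cc]
  p <- ncol(X)
  if (length(time) < p + 1L)
    stop_survmeta("fewer complete cases than coefficients + 1",
                  "survmeta_input_error")
  if (sum(event) == 0L)
    stop_survmeta("Cox model needs at least one event", "survmeta_input_error")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const))
    stop_survmeta(paste0("constant covariate(s): ",
                         paste(colnames(X)[const], collapse = ", ")),
                  "survmeta_identifiability_error")
  # center covariates for numerical stability; beta is translation-invariant
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  beta <- numeric(p)
  at0 <- cox_pl(beta, time, event, Xc, strata, ties)
  score_at_zero <- tryCatch(
    drop(t(at0$score) %*% solve(at0$info, at0$score)),
    error = function(e) NA_real_)
  ll <- at0$loglik
  trace <- ll
  cur <- at0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$score), error = function(e)
      stop_survmeta("singular information matrix: covariates may be collinear",
                    "survmeta_identifiability_error"))
    # step halving keeps the partial likelihood non-decreasing
    halves <- 0L
    repeat {
      cand <- beta + step
      nxt <- cox_pl(cand, time, event, Xc, strata, ties)
      if (is.finite(nxt$loglik) && nxt$loglik >= ll - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 30L)
        stop_survmeta("step halving failed: partial likelihood cannot increase",
                      "survmeta_convergence_error")
    }
    beta <- cand
    if (any(abs(beta) > 15))
      stop_survmeta(paste0("coefficient diverging (|beta| > 15): likely complete ",
                           "separation / monotone likelihood"),
                    "survmeta_separation_error")
    rel_change <- abs(nxt$loglik - ll) / (abs(ll) + 1e-12)
    ll <- nxt$loglik
    trace <- c(trace, ll)
    cur <- nxt
    if (max(abs(cur$score)) < tol || rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop_survmeta(paste0("Newton-Raphson did not converge in ", max_iter,
                         " iterations; log-likelihood trace: ",
                         paste(format(trace, digits = 8), collapse = " -> ")),
                  "survmeta_convergence_error")
  vc <- solve(cur$info)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta,
                 standard_errors = stats::setNames(se, colnames(X)),
                 hazard_ratios = exp(beta),
                 hr_lower = exp(beta - z * se),
                 hr_upper = exp(beta + z * se),
                 vcov = vc,
                 log_likelihood = ll,
                 loglik_trace = trace,
                 null_loglik = trace[1L],
                 score_at_zero = score_at_zero,
                 iterations = iter,
                 converged = converged,
                 ties_method = ties,
                 strata_levels = sort(unique(strata)),
                 conf_level = conf_level,
                 center = ctr,
                 n = length(time), n_events = sum(event)),
            class = "cox_model")
}

#' @export
coef.cox_model <- function(object, ...) object$coefficients

#' @export
vcov.cox_model <- function(object, ...) object$vcov

#' @export
logLik.cox_model <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cox_model <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$standard_errors,
              object$coefficients + z * object$standard_errors)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cox_model <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  lp <- drop(sweep(X, 2, object$center) %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' @export
print.cox_model <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties_method, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(summary(x)$coefficients)
  cat(sprintf("Partial log-likelihood %.4f (null %.4f), %d iterations\n",
              x$log_likelihood, x$null_loglik, x$iterations))
  invisible(x)
}

#' @export
summary.cox_model <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  tab <- data.frame(beta = object$coefficients, se = object$standard_errors,
                    hr = object$hazard_ratios, hr_lower = object$hr_lower,
                    hr_upper = object$hr_upper, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  lrt <- 2 * (object$log_likelihood - object$null_loglik)
  structure(list(coefficients = tab,
                 lrt_statistic = lrt,
                 lrt_p = stats::pchisq(lrt, nrow(tab), lower.tail = FALSE),
                 score_at_zero = object$score_at_zero,
                 n = object$n, n_events = object$n_events),
            class = "summary.cox_model")
}

#' @export
print.summary.cox_model <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("Likelihood ratio = %.3f, p = %s; score at 0 = %.3f\n",
              x$lrt_statistic, format.pval(x$lrt_p, digits = 3), x$score_at_zero))
  invisible(x)
}

#' Survival formula against a coded dataset
#'
#' @param time,event canonical time and event column names.
#' @param covariates ordered covariate column names.
#' @param strata optional stratum columns (disjoint from covariates).
#' @param endpoint_level optional event code treated as the event; otherwise
#'   the canonical 0/1 coding applies.
#' @return object of class `survival_formula`.
#' @export
survival_formula <- function(time, event, covariates = character(),
                             strata = NULL, endpoint_level = NULL) {
  if (length(intersect(covariates, strata)) > 0L)
    stop_survmeta("covariates and strata must be disjoint", "survmeta_input_error")
  structure(list(time = time, event = event, covariates = covariates,
                 strata = strata, endpoint_level = endpoint_level),
            class = "survival_formula")
}

resolve_formula <- function(ds, formula) {
  cols <- c(formula$time, formula$event, formula$covariates, formula$strata)
  absent <- setdiff(cols, names(ds$data))
  if (length(absent) > 0L)
    stop_survmeta(paste0("formula references unknown column(s): ",
                         paste(absent, collapse = ", ")),
                  "survmeta_input_error")
  ev <- ds$data[[formula$event]]
  if (!is.null(formula$endpoint_level))
    ev <- as.integer(ev == formula$endpoint_level)
  list(time = ds$data[[formula$time]], event = ev)
}

#' Grouped Kaplan-Meier curves with log-rank test from a formula
#'
#' One curve per combination of the distinct observed values of the formula's
#' covariates (numeric covariates are expanded over their unique values), plus
#' the log-rank test across those groups; strata are honoured in the test.
#' Refuses to expand past 20 groups.
#'
#' @param ds a `coded_dataset`.
#' @param formula a [survival_formula()].
#' @param conf_level passed to [km_estimate()].
#' @return object of class `km_analysis`: `curves` (a `km_curve_list`),
#'   `logrank` (a `logrank_result`, `NULL` for a single group), `groups`.
#' @export
km_by_formula <- function(ds, formula, conf_level = 0.95) {
  te <- resolve_formula(ds, formula)
  cc <- !is.na(te$time) & !is.na(te$event)
  gvars <- formula$covariates
  glab <- if (length(gvars) == 0L) rep("all", ds$n_rows)
  else {
    parts <- lapply(gvars, function(v) ds$data[[v]])
    for (pv in parts) cc <- cc & !is.na(pv)
    do.call(paste, c(lapply(seq_along(gvars), function(i)
      paste0(gvars[i], "=", parts[[i]])), sep = ", "))
  }
  strata <- if (!is.null(formula$strata)) {
    sv <- lapply(formula$strata, function(v) ds$data[[v]])
    for (s in sv) cc <- cc & !is.na(s)
    do.call(paste, c(sv, sep = "/"))
  } else NULL
  tt <- te$time[cc]; ee <- te$event[cc]; gg <- glab[cc]
  ss <- if (is.null(strata)) NULL else strata[cc]
  n_groups <- length(unique(gg))
  if (n_groups > 20L)
    stop_survmeta(paste0(n_groups, " groups would result; coarsen the ",
                         "covariates or use fit_coxph for continuous terms"),
                  "survmeta_group_explosion")
  curves <- km_estimate(tt, ee, group = if (n_groups > 1L) gg else NULL,
                        conf_level = conf_level)
  if (n_groups == 1L)
    curves <- structure(stats::setNames(list(curves), unique(gg)),
                        class = "km_curve_list")
  lr <- if (n_groups > 1L) logrank_test(tt, ee, gg, strata = ss) else NULL
  structure(list(curves = curves, logrank = lr,
                 groups = sort(unique(gg)), n = length(tt)),
            class = "km_analysis")
}

#' Cox model from a formula against a coded dataset
#'
#' @param ds a `coded_dataset`.
#' @param formula a [survival_formula()].
#' @param ... passed to [fit_coxph()].
#' @return a `cox_model`.
#' @export
coxph_by_formula <- function(ds, formula, ...) {
  te <- resolve_formula(ds, formula)
  X <- as.matrix(ds$data[, formula$covariates, drop = FALSE])
  strata <- if (!is.null(formula$strata))
    do.call(paste, c(lapply(formula$strata, function(v) ds$data[[v]]), sep = "/"))
  else NULL
  fit_coxph(te$time, te$event, X, strata = strata, ...)
}

#' @export
print.km_analysis <- function(x, ...) {
  print(x$curves)
  if (!is.null(x$logrank)) print(x$logrank)
  invisible(x)
}
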