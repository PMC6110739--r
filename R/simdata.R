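# Synthetic right-censored cohorts with known ground truth.
#
# Event times are drawn by inverse transform under a proportional-hazards
# model: T = H0^{-1}(-log U / exp(beta' x)) with an exponential or Weibull
# baseline, independent censoring (administrative cutoff, an exponential
# censoring time, or a target censoring fraction solved from the drawn event
# times), and covariates from Bernoulli / normal / categorical laws. The
# default cohort mirrors the shape of a classic adjuvant colon-cancer trial:
# treatment arm, age, nodal involvement, sex, tumour differentiation and
# local extent, with overall-survival time in months and a 0/1 death flag.

#' Specify a synthetic cohort
#'
#' @param n number of subjects.
#' @param baseline list: `list(dist = "exponential", rate = )` or
#'   `list(dist = "weibull", shape = , scale = )`.
#' @param betas named numeric vector of log-hazard-ratio effects; names must
#'   be covariate names; covariates not named get effect 0.
#' @param covariates named list of covariate laws:
#'   `list(dist = "bernoulli", p = , labels = )`,
#'   `list(dist = "normal", mean = , sd = )`, or
#'   `list(dist = "categorical", probs = , labels = )`. `labels`, when given,
#'   become the raw tokens written by [make_fixture_files()]; codes are
#'   0-based (Bernoulli/categorical).
#' @param censoring list: `list(type = "none")`,
#'   `list(type = "admin", time = )`, `list(type = "exponential", rate = )`,
#'   or `list(type = "target", fraction = )` with fraction in `[0, 1)`.
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n, baseline = list(dist = "exponential", rate = 0.03),
                     betas = numeric(),
                     covariates = list(),
                     censoring = list(type = "target", fraction = 0.5),
                     seed = 1L) {
  if (baseline$dist == "exponential" && baseline$rate <= 0)
    stop_survmeta("baseline rate must be > 0", "survmeta_spec_error")
  if (baseline$dist == "weibull" && (baseline$shape <= 0 || baseline$scale <= 0))
    stop_survmeta("Weibull shape and scale must be > 0", "survmeta_spec_error")
  if (censoring$type == "target" &&
      (censoring$fraction < 0 || censoring$fraction >= 1))
    stop_survmeta("target censoring fraction must lie in [0, 1)",
                  "survmeta_spec_error")
  bad <- setdiff(names(betas), names(covariates))
  if (length(bad) > 0L)
    stop_survmeta(paste0("betas name unknown covariate(s): ",
                         paste(bad, collapse = ", ")), "survmeta_spec_error")
  structure(list(n = n, baseline = baseline, betas = betas,
                 covariates = covariates, censoring = censoring,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Colon-trial-shaped default cohort
#'
#' 900 subjects; overall-survival time in months under an exponential baseline
#' hazard of 0.03/month; treatment arm with hazard ratio 0.7; age (years,
#' normal 60/12) and nodal count with modest positive effects; sex,
#' differentiation (3 levels) and extent (4 levels) as null covariates.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return a [sim_spec()].
#' @export
colon_like_spec <- function(n = 900L, seed = 1L) {
  sim_spec(
    n = n,
    baseline = list(dist = "exponential", rate = 0.03),
    betas = c(rx = log(0.7), age = 0.015, nodes = 0.08),
    covariates = list(
      rx = list(dist = "bernoulli", p = 0.5, labels = c("control", "treatment")),
      age = list(dist = "normal", mean = 60, sd = 12),
      nodes = list(dist = "normal", mean = 3.7, sd = 3.5),
      sex = list(dist = "bernoulli", p = 0.5, labels = c("F", "M")),
      differ = list(dist = "categorical", probs = c(0.1, 0.7, 0.2),
                    labels = c("well", "moderate", "poor")),
      extent = list(dist = "categorical", probs = c(0.02, 0.11, 0.81, 0.06),
                    labels = c("submucosa", "muscle", "serosa", "contiguous"))
    ),
    censoring = list(type = "target", fraction = 0.5),
    seed = seed
  )
}

draw_covariate <- function(cv, n) {
  switch(cv$dist,
    bernoulli = stats::rbinom(n, 1L, cv$p),
    normal = stats::rnorm(n, cv$mean, cv$sd),
    categorical = sample.int(length(cv$probs), n, replace = TRUE,
                             prob = cv$probs) - 1L,
    stop_survmeta(paste0("unknown covariate law '", cv$dist, "'"),
                  "survmeta_spec_error"))
}

#' Simulate a right-censored cohort
#'
#' @param spec a [sim_spec()].
#' @return object of class `sim_result`: `dataset` (data frame with `TimeOS`,
#'   `EventDeath` and the covariates, numeric/code-valued),
#'   `latent_event_time`, `truth` (the spec), `realized_censor_fraction`,
#'   `censor_rate` (the exponential censoring rate actually used, if any).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  covs <- lapply(spec$covariates, draw_covariate, n = n)
  X <- if (length(covs) > 0L) do.call(cbind, covs) else matrix(0, n, 0L)
  beta <- stats::setNames(numeric(length(covs)), names(covs))
  beta[names(spec$betas)] <- spec$betas
  # effects act on centred covariates so the baseline stays interpretable at
  # the cohort mean rather than at covariate zero
  lp <- if (length(covs) > 0L)
    drop(sweep(X, 2, colMeans(X)) %*% beta) else numeric(n)
  u <- stats::runif(n)
  cumhaz <- -log(u) / exp(lp)              # H0(T) = -log U / exp(beta'x)
  T_event <- switch(spec$baseline$dist,
    exponential = cumhaz / spec$baseline$rate,
    weibull = spec$baseline$scale * cumhaz^(1 / spec$baseline$shape),
    stop_survmeta("unknown baseline distribution", "survmeta_spec_error"))
  cens <- spec$censoring
  censor_rate <- NA_real_
  C <- switch(cens$type,
    none = rep(Inf, n),
    admin = rep(cens$time, n),
    exponential = { censor_rate <- cens$rate; stats::rexp(n, cens$rate) },
    target = {
      if (cens$fraction == 0) rep(Inf, n) else {
        # choose the exponential censoring rate c so that the expected event
        # fraction E[exp(-c T)] over the drawn latent times hits the target
        f <- function(cr) mean(exp(-cr * T_event)) - (1 - cens$fraction)
        censor_rate <- stats::uniroot(f, lower = 1e-12,
                                      upper = 1e6 / stats::median(T_event),
                                      tol = 1e-12)$root
        stats::rexp(n, censor_rate)
      }
    },
    stop_survmeta("unknown censoring type", "survmeta_spec_error"))
  time <- pmin(T_event, C)
  event <- as.integer(T_event <= C)
  dataset <- data.frame(TimeOS = time, EventDeath = event,
                        stringsAsFactors = FALSE)
  for (nm in names(covs)) dataset[[nm]] <- covs[[nm]]
  structure(list(dataset = dataset, latent_event_time = T_event,
                 truth = spec, realized_censor_fraction = mean(event == 0),
                 censor_rate = censor_rate),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated cohort: n =", nrow(x$dataset),
      sprintf(", censored %.1f%%", 100 * x$realized_censor_fraction), "\n")
  invisible(x)
}

# bundle describing a sim_result, built from the generating spec (categorical
# laws become layer-3 dictionaries with their labels as raw tokens)
sim_bundle <- function(spec) {
  cn <- names(spec$covariates)
  meas <- vapply(spec$covariates, function(cv)
    if (cv$dist == "normal") "ratio" else "nominal", "")
  l2 <- layer2_specs(c("TimeOS", "EventDeath", cn),
                     c("ratio", "nominal", unname(meas)),
                     c("time", "event", rep("covariate", length(cn))))
  l3v <- "EventDeath"; l3c <- c(0L, 1L)
  l3v <- rep("EventDeath", 2L); l3t <- c("0|alive", "1|dead")
  l3d <- c("alive", "dead")
  for (nm in cn) {
    cv <- spec$covariates[[nm]]
    if (cv$dist == "normal") next
    k <- if (cv$dist == "bernoulli") 2L else length(cv$probs)
    labels <- cv$labels %||% as.character(seq_len(k) - 1L)
    codes <- seq_len(k) - 1L
    toks <- ifelse(labels == as.character(codes), as.character(codes),
                   paste(codes, labels, sep = "|"))
    l3v <- c(l3v, rep(nm, k)); l3c <- c(l3c, codes)
    l3t <- c(l3t, toks); l3d <- c(l3d, labels)
  }
  metadata_bundle(layer1_roles("TimeOS", "EventDeath"), l2,
                  layer3_map(l3v, l3c, l3t, l3d))
}

#' Write a simulated cohort as fixture files
#'
#' Produces `Dataset.csv` plus the three metadata layer CSVs in `dir`.
#' Categorical covariates are written as their raw display tokens (e.g. sex as
#' `M`/`F`) so that loading exercises the layer-3 recoding; the round trip
#' through [read_metadata()] and [load_dataset()] reproduces the simulated
#' codes exactly.
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
make_fixture_files <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- result$truth
  bundle <- sim_bundle(spec)
  raw <- result$dataset
  for (nm in names(spec$covariates)) {
    cv <- spec$covariates[[nm]]
    if (cv$dist == "normal" || is.null(cv$labels)) next
    raw[[nm]] <- cv$labels[raw[[nm]] + 1L]
  }
  # print doubles at 17 significant digits so the text round-trips losslessly
  for (nm in names(raw))
    if (is.double(raw[[nm]])) raw[[nm]] <- sprintf("%.17g", raw[[nm]])
  dpath <- file.path(dir, "Dataset.csv")
  utils::write.csv(raw, dpath, row.names = FALSE, quote = FALSE)
  lpaths <- write_metadata(bundle, dir)
  invisible(c(dataset = dpath, lpaths))
}
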