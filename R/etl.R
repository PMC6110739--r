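# Metadata-driven import and cohort filtering.
#
# load_dataset() turns a raw CSV into a coded analysis table: layer-1 aliases
# rename columns, layer-3 dictionaries recode categorical tokens to integer
# codes, continuous columns are coerced to numeric, and every unparseable or
# unmapped cell becomes missing and is counted. apply_filters() implements
# conjunctive inclusion/exclusion criteria with first-failure attribution of
# excluded rows, so the exclusion flow of a cohort diagram can be read off
# directly.

FILTER_OPS <- c("==", "!=", "<", "<=", ">", ">=", "in", "not-in",
                "missing", "not-missing")

#' Load and recode a dataset under a metadata bundle
#'
#' @param path CSV file, one row per subject, header required.
#' @param bundle a [metadata_bundle()] describing the file.
#' @return an object of class `coded_dataset`: list with `data` (typed
#'   data frame, canonical names), `missing_mask` (logical matrix),
#'   `n_rows`, `bundle`, `provenance` and `recode_report` (per-variable count
#'   of cells that became missing during recoding).
#' @export
load_dataset <- function(path, bundle) {
  if (!file.exists(path))
    stop_survmeta(paste0("dataset not found: ", path), "survmeta_input_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  coded_dataset(raw, bundle, source = path)
}

#' Recode an in-memory raw table under a metadata bundle
#'
#' Workhorse behind [load_dataset()]; accepts any data frame of raw values.
#'
#' @param raw data frame of raw (character or typed) values.
#' @param bundle a [metadata_bundle()].
#' @param source provenance label.
#' @return a `coded_dataset` (see [load_dataset()]).
#' @export
coded_dataset <- function(raw, bundle, source = "<memory>") {
  names(raw) <- canonical_name(bundle$layer1, names(raw))
  l2 <- bundle$layer2[bundle$layer2$role != "ignore", , drop = FALSE]
  absent <- setdiff(l2$name, names(raw))
  if (length(absent) > 0L)
    stop_survmeta(paste0("layer-2 column(s) absent from data: ",
                         paste(absent, collapse = ", ")),
                  "survmeta_input_error")
  n <- nrow(raw)
  out <- list()
  recode_report <- stats::setNames(integer(nrow(l2)), l2$name)
  for (j in seq_len(nrow(l2))) {
    nm <- l2$name[j]
    x <- trim(raw[[nm]])
    blank <- is.na(x) | x == "" | x == "NA"
    if (l2$analysis_class[j] == "continuous") {
      v <- suppressWarnings(as.numeric(x))
      v[blank] <- NA_real_
      recode_report[nm] <- sum(is.na(v) & !blank)
    } else {
      map <- bundle$layer3[bundle$layer3$variable == nm, , drop = FALSE]
      if (nrow(map) > 0L) {
        toks <- lapply(map$tokens, split_tokens)
        lookup <- stats::setNames(rep(map$code, lengths(toks)), unlist(toks))
        v <- unname(lookup[x])
      } else {
        v <- suppressWarnings(as.integer(x))
      }
      v[blank] <- NA_integer_
      recode_report[nm] <- sum(is.na(v) & !blank)
    }
    out[[nm]] <- v
  }
  data <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  tcol <- canonical_name(bundle$layer1, bundle$layer1$time_column)
  ecol <- canonical_name(bundle$layer1, bundle$layer1$event_column)
  if (any(data[[tcol]] < 0, na.rm = TRUE))
    stop_survmeta(paste0("negative values in time column '", tcol,
                         "': corrupt data"), "survmeta_load_error")
  ebad <- !is.na(data[[ecol]]) & !data[[ecol]] %in% c(0L, 1L)
  if (any(ebad))
    stop_survmeta(paste0("event column '", ecol, "' has codes outside {0,1} in rows ",
                         paste(utils::head(which(ebad), 10L), collapse = ", ")),
                  "survmeta_load_error")
  if (recode_report[ecol] > 0L)
    warn_survmeta(paste0(recode_report[ecol], " unmappable value(s) in event column '",
                         ecol, "' set to missing"), "survmeta_recode_warning")
  structure(list(data = data,
                 missing_mask = is.na(as.matrix(data)),
                 n_rows = n,
                 bundle = bundle,
                 recode_report = recode_report,
                 provenance = list(source = source,
                                   bundle_hash = content_hash(bundle))),
            class = "coded_dataset")
}

#' @export
print.coded_dataset <- function(x, ...) {
  cat("Coded dataset:", x$n_rows, "subjects,", ncol(x$data), "variables\n")
  cat("  source:", x$provenance$source, "\n")
  mr <- missing_report(x)
  nm <- sum(mr$n_missing)
  cat("  missing cells:", nm, sprintf("(%.1f%%)", 100 * nm / length(x$missing_mask)), "\n")
  invisible(x)
}

#' Per-variable missingness report
#'
#' @param ds a `coded_dataset`.
#' @return data frame with `variable`, `n_missing`, `fraction`.
#' @export
missing_report <- function(ds) {
  nm <- colSums(ds$missing_mask)
  data.frame(variable = colnames(ds$missing_mask),
             n_missing = as.integer(nm),
             fraction = if (ds$n_rows > 0L) unname(nm) / ds$n_rows else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a filter criterion
#'
#' Order comparisons (`<`, `<=`, `>`, `>=`) are only legal for continuous
#' variables; `in`/`not-in` take a code or value list; `missing`/`not-missing`
#' take no value. Missing cells fail every criterion except
#' `missing`/`not-missing`.
#'
#' @param variable column name (canonical).
#' @param op one of `==`, `!=`, `<`, `<=`, `>`, `>=`, `in`, `not-in`,
#'   `missing`, `not-missing`.
#' @param value comparison literal or vector (ignored for missingness ops).
#' @return an object of class `filter_criterion`.
#' @export
filter_criterion <- function(variable, op, value = NULL) {
  if (!op %in% FILTER_OPS)
    stop_survmeta(paste0("unknown filter op '", op, "'"), "survmeta_filter_error")
  structure(list(variable = variable, op = op, value = value),
            class = "filter_criterion")
}

#' Parse a filter expression string
#'
#' Grammar used by the command line: `"age<65"`, `"extent in 2,3"`,
#' `"sex == 1"`, `"nodes not-missing"`.
#'
#' @param text one filter expression.
#' @return a [filter_criterion()].
#' @export
parse_filter <- function(text) {
  s <- trim(text)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+)\\s+(not-missing|missing)\\s*$", s))[[1L]]
  if (length(m) == 3L) return(filter_criterion(m[2L], m[3L]))
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+)\\s+(not-in|in)\\s+(.+)$", s))[[1L]]
  if (length(m) == 4L) {
    vals <- trim(strsplit(m[4L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    return(filter_criterion(m[2L], m[3L], if (anyNA(num)) vals else num))
  }
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+)\\s*(==|!=|<=|>=|<|>)\\s*(.+)$", s))[[1L]]
  if (length(m) == 4L) {
    val <- trim(m[4L])
    num <- suppressWarnings(as.numeric(val))
    return(filter_criterion(m[2L], m[3L], if (is.na(num)) val else num))
  }
  stop_survmeta(paste0("cannot parse filter expression: '", text, "'"),
                "survmeta_filter_error")
}

# evaluate one criterion on the coded data; NA cells fail unless the op is
# about missingness
eval_criterion <- function(crit, ds) {
  l2 <- ds$bundle$layer2
  if (!crit$variable %in% names(ds$data))
    stop_survmeta(paste0("filter references unknown variable '", crit$variable, "'"),
                  "survmeta_filter_error")
  cls <- l2$analysis_class[l2$name == crit$variable]
  x <- ds$data[[crit$variable]]
  if (crit$op %in% c("<", "<=", ">", ">=") && cls != "continuous")
    stop_survmeta(paste0("order comparison on categorical variable '",
                         crit$variable, "'"), "survmeta_filter_error")
  pass <- switch(crit$op,
    "missing" = is.na(x),
    "not-missing" = !is.na(x),
    "==" = !is.na(x) & x == crit$value,
    "!=" = !is.na(x) & x != crit$value,
    "<" = !is.na(x) & x < crit$value,
    "<=" = !is.na(x) & x <= crit$value,
    ">" = !is.na(x) & x > crit$value,
    ">=" = !is.na(x) & x >= crit$value,
    "in" = !is.na(x) & x %in% crit$value,
    "not-in" = !is.na(x) & !x %in% crit$value)
  pass
}

#' Apply inclusion/exclusion criteria
#'
#' Criteria are conjunctive and applied in order: a row is included iff it
#' satisfies every criterion; each excluded row is attributed to the first
#' criterion it fails, so the per-criterion counts describe a sequential
#' exclusion flow and always sum to the total excluded.
#'
#' @param ds a `coded_dataset`.
#' @param criteria list of [filter_criterion()] (or strings for
#'   [parse_filter()]).
#' @return object of class `filter_outcome`: `included` (a `coded_dataset`),
#'   `n_excluded_per_criterion`, `n_excluded_total`, `n_included`.
#' @export
apply_filters <- function(ds, criteria) {
  criteria <- lapply(criteria, function(cr)
    if (is.character(cr)) parse_filter(cr) else cr)
  n <- ds$n_rows
  keep <- rep(TRUE, n)
  attributed <- rep(NA_integer_, n)
  for (i in seq_along(criteria)) {
    pass <- eval_criterion(criteria[[i]], ds)
    newly <- keep & !pass
    attributed[newly & is.na(attributed)] <- i
    keep <- keep & pass
  }
  inc <- ds
  inc$data <- ds$data[keep, , drop = FALSE]
  rownames(inc$data) <- NULL
  inc$missing_mask <- ds$missing_mask[keep, , drop = FALSE]
  inc$n_rows <- sum(keep)
  per <- if (length(criteria) > 0L)
    vapply(seq_along(criteria), function(i) sum(attributed == i, na.rm = TRUE), integer(1))
  else integer(0)
  structure(list(included = inc,
                 n_excluded_per_criterion = per,
                 n_excluded_total = n - sum(keep),
                 n_included = sum(keep)),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat("Filter outcome: ", x$n_included, " included, ",
      x$n_excluded_total, " excluded\n", sep = "")
  if (length(x$n_excluded_per_criterion) > 0L)
    cat("  excluded per criterion (first failure):",
        paste(x$n_excluded_per_criterion, collapse = ", "), "\n")
  invisible(x)
}
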