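# Three-layer metadata codebook.
#
# Layer 1 maps raw column names onto the standard roles of a survival table
# (observed time, event flag, optional subject id) and can alias further raw
# columns to canonical names. Layer 2 records the measurement scale of every
# analysis column (nominal / ordinal / interval / ratio) and its role. Layer 3
# is the dictionary translating raw categorical tokens into integer codes.
# All downstream stages consume the bundle, never the raw files directly.

MEASUREMENTS <- c("nominal", "ordinal", "interval", "ratio")
ROLES <- c("time", "event", "covariate", "stratifier", "ignore")

#' Derive the binary analysis class from a measurement scale
#'
#' Interval and ratio scales are analysed as continuous variables; nominal and
#' ordinal scales as categorical. The mapping is total and deterministic.
#'
#' @param measurement character vector of measurement scales
#'   (`"nominal"`, `"ordinal"`, `"interval"` or `"ratio"`).
#' @return character vector, `"continuous"` or `"categorical"`.
#' @export
analysis_class <- function(measurement) {
  bad <- setdiff(unique(measurement), MEASUREMENTS)
  if (length(bad) > 0L)
    stop_survmeta(paste0("unknown measurement scale(s): ",
                         paste(bad, collapse = ", ")),
                  "survmeta_schema_error")
  ifelse(measurement %in% c("interval", "ratio"), "continuous", "categorical")
}

#' Layer-1 column roles
#'
#' @param time_column raw column name carrying the observed time.
#' @param event_column raw column name carrying the event flag.
#' @param id_column optional subject identifier column.
#' @param extend_columns named character vector mapping raw column names to
#'   canonical names (e.g. `c(OS_months = "TimeOS")`).
#' @return an object of class `layer1_roles`.
#' @export
layer1_roles <- function(time_column, event_column, id_column = NULL,
                         extend_columns = character()) {
  if (identical(time_column, event_column))
    stop_survmeta("time_column and event_column must differ",
                  "survmeta_schema_error")
  if (length(extend_columns) > 0L &&
      (is.null(names(extend_columns)) || anyDuplicated(extend_columns) ||
       anyDuplicated(names(extend_columns))))
    stop_survmeta("extend_columns must be a named map with unique raw and canonical names",
                  "survmeta_schema_error")
  structure(list(time_column = time_column, event_column = event_column,
                 id_column = id_column,
                 extend_columns = extend_columns),
            class = "layer1_roles")
}

#' Layer-2 variable specifications
#'
#' @param name column names (canonical, i.e. after layer-1 aliasing).
#' @param measurement measurement scale per column.
#' @param role role per column (`time`, `event`, `covariate`, `stratifier`,
#'   `ignore`).
#' @return a `data.frame` with columns `name`, `measurement`, `role` and the
#'   derived `analysis_class`.
#' @export
layer2_specs <- function(name, measurement, role = "covariate") {
  role <- rep_len(role, length(name))
  bad_role <- setdiff(unique(role), ROLES)
  if (length(bad_role) > 0L)
    stop_survmeta(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
                  "survmeta_schema_error")
  cls <- analysis_class(measurement)
  if (anyDuplicated(name))
    stop_survmeta("layer 2 variable names must be unique", "survmeta_schema_error")
  time_bad <- role == "time" & cls != "continuous"
  if (any(time_bad))
    stop_survmeta(paste0("time variable must be continuous (interval/ratio): ",
                         paste(name[time_bad], collapse = ", ")),
                  "survmeta_schema_error")
  event_bad <- role == "event" & cls != "categorical"
  if (any(event_bad))
    stop_survmeta(paste0("event variable must be categorical (nominal/ordinal): ",
                         paste(name[event_bad], collapse = ", ")),
                  "survmeta_schema_error")
  data.frame(name = name, measurement = measurement, role = role,
             analysis_class = cls, stringsAsFactors = FALSE)
}

#' Layer-3 category dictionary
#'
#' One row per (variable, code). `tokens` lists the raw tokens accepted for
#' the code, pipe-separated; matching is case-sensitive and whitespace-trimmed
#' (so `{1, m, M}` are three distinct tokens mapping to one code).
#'
#' @param variable column name the entry belongs to.
#' @param code integer code the tokens map onto.
#' @param tokens accepted raw tokens, pipe-separated string per row.
#' @param display human-readable label per code.
#' @return a `data.frame` with the four columns above.
#' @export
layer3_map <- function(variable, code, tokens, display = as.character(code)) {
  df <- data.frame(variable = as.character(variable), code = as.integer(code),
                   tokens = as.character(tokens),
                   display = as.character(display), stringsAsFactors = FALSE)
  for (v in unique(df$variable)) {
    rows <- df[df$variable == v, ]
    if (anyDuplicated(rows$code))
      stop_survmeta(paste0("duplicate codes for variable '", v, "'"),
                    "survmeta_schema_error")
    toks <- unlist(lapply(rows$tokens, split_tokens))
    if (anyDuplicated(toks)) {
      dup <- toks[duplicated(toks)][1L]
      stop_survmeta(paste0("token '", dup, "' claimed by two codes of variable '",
                           v, "'"), "survmeta_schema_error")
    }
  }
  df
}

split_tokens <- function(tokens) trim(strsplit(tokens, "|", fixed = TRUE)[[1L]])

#' Assemble a metadata bundle
#'
#' Ties the three layers together and enforces the cross-layer invariants:
#' every layer-1 and layer-3 column appears in layer 2, and layer 2 carries
#' exactly one `time` and one `event` role.
#'
#' @param layer1 a [layer1_roles()] object.
#' @param layer2 a [layer2_specs()] data frame.
#' @param layer3 a [layer3_map()] data frame (possibly zero rows).
#' @return an object of class `metadata_bundle`.
#' @export
metadata_bundle <- function(layer1, layer2, layer3 = layer3_map(character(), integer(), character())) {
  b <- structure(list(layer1 = layer1, layer2 = layer2, layer3 = layer3),
                 class = "metadata_bundle")
  problems <- check_bundle(b)
  errs <- problems[vapply(problems, function(p) p$severity == "error", logical(1))]
  if (length(errs) > 0L)
    stop_survmeta(paste0("invalid metadata bundle: ",
                         paste(vapply(errs, `[[`, "", "message"), collapse = "; ")),
                  "survmeta_schema_error")
  b
}

# canonical name of a layer-1 raw column (identity unless aliased)
canonical_name <- function(layer1, raw) {
  ext <- layer1$extend_columns
  ifelse(raw %in% names(ext), unname(ext[raw]), raw)
}

# internal: all invariant checks as report entries, never exceptions
check_bundle <- function(b) {
  problems <- list()
  add <- function(severity, variable, message)
    problems[[length(problems) + 1L]] <<- list(severity = severity,
                                               variable = variable,
                                               message = message)
  l1 <- b$layer1; l2 <- b$layer2; l3 <- b$layer3
  tcan <- canonical_name(l1, l1$time_column)
  ecan <- canonical_name(l1, l1$event_column)
  if (!tcan %in% l2$name)
    add("error", tcan, paste0("time column '", tcan, "' missing from layer 2"))
  if (!ecan %in% l2$name)
    add("error", ecan, paste0("event column '", ecan, "' missing from layer 2"))
  n_time <- sum(l2$role == "time"); n_event <- sum(l2$role == "event")
  if (n_time != 1L)
    add("error", NA_character_, paste0("layer 2 must have exactly one time role, found ", n_time))
  if (n_event != 1L)
    add("error", NA_character_, paste0("layer 2 must have exactly one event role, found ", n_event))
  if (n_time == 1L && l2$name[l2$role == "time"] != tcan)
    add("error", tcan, "layer-1 time column does not carry the layer-2 time role")
  if (n_event == 1L && l2$name[l2$role == "event"] != ecan)
    add("error", ecan, "layer-1 event column does not carry the layer-2 event role")
  for (v in unique(l3$variable)) {
    if (!v %in% l2$name) {
      add("error", v, paste0("layer-3 variable '", v, "' missing from layer 2"))
    } else if (l2$analysis_class[l2$name == v] != "categorical") {
      add("error", v, paste0("layer-3 variable '", v, "' is not categorical in layer 2"))
    }
  }
  problems
}

#' Read a metadata bundle from its three layer files
#'
#' The physical schema is three headered CSVs: `layer1.csv` with columns
#' `(role, raw_column, canonical_name)`, `layer2.csv` with
#' `(name, measurement, role)` and `layer3.csv` with
#' `(variable, code, tokens, display)`, tokens pipe-separated.
#'
#' @param layer1_path,layer2_path,layer3_path paths to the three CSVs.
#' @return a validated [metadata_bundle()].
#' @export
read_metadata <- function(layer1_path, layer2_path, layer3_path) {
  for (p in c(layer1_path, layer2_path, layer3_path))
    if (!file.exists(p))
      stop_survmeta(paste0("metadata file not found: ", p), "survmeta_input_error")
  l1 <- utils::read.csv(layer1_path, stringsAsFactors = FALSE, colClasses = "character")
  need1 <- c("role", "raw_column", "canonical_name")
  if (!all(need1 %in% names(l1)))
    stop_survmeta("layer1.csv must have columns role, raw_column, canonical_name",
                  "survmeta_schema_error")
  pick <- function(role) {
    r <- l1[l1$role == role, , drop = FALSE]
    if (nrow(r) > 1L)
      stop_survmeta(paste0("layer1.csv: multiple '", role, "' rows"),
                    "survmeta_schema_error")
    if (nrow(r) == 0L) NULL else r$raw_column[1L]
  }
  tc <- pick("time"); ec <- pick("event")
  if (is.null(tc) || is.null(ec))
    stop_survmeta("layer1.csv must define one time row and one event row",
                  "survmeta_schema_error")
  ext_rows <- l1[l1$role == "extend", , drop = FALSE]
  ext <- stats::setNames(ext_rows$canonical_name, ext_rows$raw_column)
  # time/event rows may alias too
  for (role in c("time", "event", "id")) {
    r <- l1[l1$role == role, , drop = FALSE]
    if (nrow(r) == 1L && nzchar(r$canonical_name[1L]) &&
        r$canonical_name[1L] != r$raw_column[1L])
      ext[r$raw_column[1L]] <- r$canonical_name[1L]
  }
  layer1 <- layer1_roles(tc, ec, id_column = pick("id"),
                         extend_columns = ext)

  l2 <- utils::read.csv(layer2_path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("name", "measurement", "role") %in% names(l2)))
    stop_survmeta("layer2.csv must have columns name, measurement, role",
                  "survmeta_schema_error")
  layer2 <- layer2_specs(l2$name, l2$measurement, l2$role)

  l3raw <- utils::read.csv(layer3_path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(l3raw) > 0L && !all(c("variable", "code", "tokens") %in% names(l3raw)))
    stop_survmeta("layer3.csv must have columns variable, code, tokens[, display]",
                  "survmeta_schema_error")
  code <- suppressWarnings(as.integer(l3raw$code))
  if (nrow(l3raw) > 0L && anyNA(code)) {
    bad <- which(is.na(code))[1L]
    stop_survmeta(paste0("layer3.csv row ", bad, ": code '", l3raw$code[bad],
                         "' is not an integer"), "survmeta_schema_error")
  }
  disp <- if ("display" %in% names(l3raw)) l3raw$display else as.character(code)
  layer3 <- layer3_map(l3raw$variable, code, l3raw$tokens, disp)
  metadata_bundle(layer1, layer2, layer3)
}

#' Write a metadata bundle to a directory
#'
#' Produces `layer1.csv`, `layer2.csv` and `layer3.csv` in the dialect read by
#' [read_metadata()]; the round trip is the identity on valid bundles.
#'
#' @param bundle a [metadata_bundle()].
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_metadata <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  l1 <- bundle$layer1
  rows <- data.frame(role = c("time", "event"),
                     raw_column = c(l1$time_column, l1$event_column),
                     canonical_name = c(canonical_name(l1, l1$time_column),
                                        canonical_name(l1, l1$event_column)),
                     stringsAsFactors = FALSE)
  if (!is.null(l1$id_column))
    rows <- rbind(rows, data.frame(role = "id", raw_column = l1$id_column,
                                   canonical_name = canonical_name(l1, l1$id_column)))
  ext <- l1$extend_columns
  ext <- ext[!names(ext) %in% c(l1$time_column, l1$event_column, l1$id_column)]
  if (length(ext) > 0L)
    rows <- rbind(rows, data.frame(role = "extend", raw_column = names(ext),
                                   canonical_name = unname(ext)))
  p1 <- file.path(dir, "layer1.csv")
  p2 <- file.path(dir, "layer2.csv")
  p3 <- file.path(dir, "layer3.csv")
  utils::write.csv(rows, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$layer2[, c("name", "measurement", "role")], p2,
                   row.names = FALSE, quote = FALSE)
  l3 <- bundle$layer3
  l3 <- l3[order(l3$variable, l3$code), , drop = FALSE]
  utils::write.csv(l3, p3, row.names = FALSE, quote = FALSE)
  invisible(c(layer1 = p1, layer2 = p2, layer3 = p3))
}

#' Auto-generate metadata from a raw table
#'
#' Every column receives a layer-2 spec. The inference rule: a numeric column
#' with more than `k` distinct non-missing values is `ratio`/continuous;
#' anything else is `nominal`/categorical with an auto-built layer-3 map
#' (codes are the values themselves when they are small integers, otherwise
#' 0-based in sorted token order). Time and event columns are found by name
#' (`time`, `event`/`status`/`death`, case-insensitive) unless given
#' explicitly; explicit `overrides` win over inference.
#'
#' @param raw_table a data frame with at least one row and named columns.
#' @param time_column,event_column,id_column optional explicit role columns.
#' @param overrides optional named list; each element a list with any of
#'   `measurement`, `role` for that column.
#' @param k distinct-value threshold for the numeric-categorical rule
#'   (default 6).
#' @return a validated [metadata_bundle()].
#' @export
generate_metadata <- function(raw_table, time_column = NULL, event_column = NULL,
                              id_column = NULL, overrides = list(), k = 6) {
  if (!is.data.frame(raw_table) || nrow(raw_table) == 0L)
    stop_survmeta("raw table must be a data frame with at least one row",
                  "survmeta_input_error")
  cols <- names(raw_table)
  bad_ovr <- setdiff(names(overrides), cols)
  if (length(bad_ovr) > 0L)
    stop_survmeta(paste0("override references absent column(s): ",
                         paste(bad_ovr, collapse = ", ")),
                  "survmeta_input_error")
  find_by <- function(pattern) {
    hit <- grep(pattern, cols, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) NULL else hit[1L]
  }
  time_column <- time_column %||% find_by("time")
  if (is.null(event_column)) {
    hits <- grep("event|status|death", cols, ignore.case = TRUE, value = TRUE)
    hits <- setdiff(hits, time_column)
    event_column <- if (length(hits) > 0L) hits[1L] else NULL
  }
  if (is.null(time_column) || is.null(event_column))
    stop_survmeta("cannot infer time/event columns from names; pass time_column/event_column",
                  "survmeta_input_error")

  meas <- character(length(cols)); role <- character(length(cols))
  l3v <- character(); l3c <- integer(); l3t <- character(); l3d <- character()
  for (i in seq_along(cols)) {
    col <- cols[i]
    x <- raw_table[[col]]
    xnum <- suppressWarnings(as.numeric(as.character(x)))
    numericish <- !all(is.na(xnum)) && all(is.na(xnum) == (is.na(x) | trim(x) == ""))
    vals <- x[!is.na(x) & trim(x) != ""]
    ndist <- length(unique(vals))
    if (col == time_column) {
      meas[i] <- "ratio"; role[i] <- "time"
    } else if (identical(col, id_column)) {
      meas[i] <- "nominal"; role[i] <- "ignore"
    } else {
      continuous <- numericish && ndist > k
      meas[i] <- if (continuous) "ratio" else "nominal"
      role[i] <- if (col == event_column) "event" else "covariate"
    }
    ovr <- overrides[[col]]
    if (!is.null(ovr)) {
      if (!is.null(ovr$measurement)) meas[i] <- ovr$measurement
      if (!is.null(ovr$role)) role[i] <- ovr$role
    }
    if (analysis_class(meas[i]) == "categorical" && role[i] != "ignore") {
      toks <- sort(unique(trim(vals)))
      toks <- toks[toks != ""]
      toknum <- suppressWarnings(as.numeric(toks))
      codes <- if (!anyNA(toknum) && all(is_wholenumber(toknum)) &&
                   !anyDuplicated(as.integer(toknum)))
        as.integer(toknum) else seq_along(toks) - 1L
      ord <- order(codes)
      l3v <- c(l3v, rep(col, length(toks)))
      l3c <- c(l3c, codes[ord]); l3t <- c(l3t, toks[ord]); l3d <- c(l3d, toks[ord])
    }
  }
  metadata_bundle(layer1_roles(time_column, event_column, id_column = id_column),
                  layer2_specs(cols, meas, role),
                  layer3_map(l3v, l3c, l3t, l3d))
}

#' Validate a bundle against a raw table
#'
#' Re-checks every bundle invariant and scans the table: raw columns absent
#' from layer 2 are warnings (they will be ignored on load); values in a
#' categorical column not covered by its layer-3 map are errors naming the
#' value; a layer-2 column missing from the table is an error.
#'
#' @param bundle a [metadata_bundle()].
#' @param raw_table the raw data frame (pre-aliasing column names accepted).
#' @return an object of class `validation_report`: list with `errors`
#'   (data.frame severity/variable/message) and `is_valid`.
#' @export
validate_metadata <- function(bundle, raw_table) {
  problems <- check_bundle(bundle)
  add <- function(severity, variable, message)
    problems[[length(problems) + 1L]] <<- list(severity = severity,
                                               variable = variable,
                                               message = message)
  canon <- canonical_name(bundle$layer1, names(raw_table))
  for (i in seq_along(canon)) {
    if (!canon[i] %in% bundle$layer2$name)
      add("warning", canon[i],
          paste0("column '", canon[i], "' not in layer 2; it will be ignored"))
  }
  for (j in seq_len(nrow(bundle$layer2))) {
    nm <- bundle$layer2$name[j]
    if (bundle$layer2$role[j] == "ignore") next
    if (!nm %in% canon) {
      add("error", nm, paste0("layer-2 column '", nm, "' absent from the table"))
      next
    }
    x <- trim(raw_table[[which(canon == nm)[1L]]])
    x <- x[!is.na(x) & x != ""]
    if (bundle$layer2$analysis_class[j] == "categorical") {
      map <- bundle$layer3[bundle$layer3$variable == nm, , drop = FALSE]
      if (nrow(map) > 0L) {
        accepted <- unlist(lapply(map$tokens, split_tokens))
        unmapped <- setdiff(unique(x), accepted)
        for (u in unmapped)
          add("error", nm, paste0("value '", u, "' in '", nm,
                                  "' not covered by its layer-3 map"))
      } else {
        nonint <- unique(x[is.na(suppressWarnings(as.integer(x)))])
        for (u in nonint)
          add("error", nm, paste0("value '", u, "' in unmapped categorical '",
                                  nm, "' is not an integer code"))
      }
    } else {
      bad <- unique(x[is.na(suppressWarnings(as.numeric(x)))])
      for (u in bad)
        add("warning", nm, paste0("non-numeric value '", u, "' in continuous '",
                                  nm, "' will load as missing"))
    }
  }
  errs <- if (length(problems) == 0L)
    data.frame(severity = character(), variable = character(),
               message = character(), stringsAsFactors = FALSE)
  else
    data.frame(severity = vapply(problems, `[[`, "", "severity"),
               variable = vapply(problems, function(p) as.character(p$variable %||% NA), ""),
               message = vapply(problems, `[[`, "", "message"),
               stringsAsFactors = FALSE)
  structure(list(errors = errs, is_valid = !any(errs$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Metadata validation:", if (x$is_valid) "VALID" else "INVALID", "\n")
  if (nrow(x$errors) > 0L) {
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [%s] %s\n", x$errors$severity[i], x$errors$message[i]))
  }
  invisible(x)
}

#' @export
print.metadata_bundle <- function(x, ...) {
  cat("Metadata bundle\n")
  cat("  time: ", canonical_name(x$layer1, x$layer1$time_column),
      "   event: ", canonical_name(x$layer1, x$layer1$event_column), "\n", sep = "")
  cat("  layer 2: ", nrow(x$layer2), " variables (",
      sum(x$layer2$analysis_class == "continuous"), " continuous, ",
      sum(x$layer2$analysis_class == "categorical"), " categorical)\n", sep = "")
  cat("  layer 3: ", nrow(x$layer3), " code entries over ",
      length(unique(x$layer3$variable)), " variables\n", sep = "")
  invisible(x)
}
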