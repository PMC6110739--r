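# Publication-style rendering of demographic tables and survival curves:
# CSV and markdown for tables, a right-continuous step plot with censor marks
# and confidence bands plus a companion CSV for curves. Small p-values are
# displayed with a floor ("<0.001") rather than in scientific notation.

#' Rendering options
#'
#' @param decimals digits for statistics (default 3 for p and tests, 1 for
#'   descriptives).
#' @param p_floor smallest displayed p-value, in `(0, 0.01]`; smaller values
#'   render as `"<floor"`.
#' @param formats subset of `c("csv", "markdown", "plot")`.
#' @return object of class `render_options`.
#' @export
render_options <- function(decimals = list(p = 3, stat = 3, desc = 1, pct = 1),
                           p_floor = 0.001,
                           formats = c("csv", "markdown", "plot")) {
  if (p_floor <= 0 || p_floor > 0.01)
    stop_survmeta("p_floor must lie in (0, 0.01]", "survmeta_input_error")
  structure(list(decimals = decimals, p_floor = p_floor, formats = formats),
            class = "render_options")
}

#' Format a p-value with the floor convention
#'
#' @param p numeric p-values.
#' @param opts a [render_options()].
#' @return character vector, e.g. `"0.040"` or `"<0.001"`.
#' @export
format_p <- function(p, opts = render_options()) {
  d <- opts$decimals$p
  ifelse(is.na(p), "-",
         ifelse(p < opts$p_floor,
                paste0("<", format(opts$p_floor, scientific = FALSE)),
                formatC(p, digits = d, format = "f")))
}

table1_frame <- function(table, opts = render_options()) {
  dd <- opts$decimals$desc; dp <- opts$decimals$pct
  rows <- list()
  groups <- as.character(table$strat_levels)
  for (v in names(table$continuous_rows)) {
    r <- table$continuous_rows[[v]]
    row <- list(section = "continuous", variable = v, level = "")
    for (g in groups) {
      s <- r$group_summaries[[g]]
      row[[paste0("group_", g)]] <- if (is.null(s)) "" else
        sprintf(paste0("%.", dd, "f (%.", dd, "f) [%.", dd, "f-%.", dd, "f] n=%d"),
                s$mean, s$sd, s$min, s$max, s$n)
    }
    row$test <- if (isTRUE(r$untestable)) "untestable" else r$test$selected
    row$statistic <- if (is.na(r$statistic)) "" else
      formatC(r$statistic, digits = opts$decimals$stat, format = "f")
    row$p <- format_p(r$p_value, opts)
    rows[[length(rows) + 1L]] <- row
  }
  for (v in names(table$categorical_rows)) {
    r <- table$categorical_rows[[v]]
    if (isTRUE(r$untestable)) {
      row <- list(section = "categorical", variable = v, level = "")
      for (g in groups) row[[paste0("group_", g)]] <- ""
      row$test <- "untestable"; row$statistic <- ""; row$p <- "-"
      rows[[length(rows) + 1L]] <- row
      next
    }
    levels <- r$group_summaries[[1L]]$levels
    for (li in seq_along(levels)) {
      row <- list(section = "categorical", variable = v, level = levels[li])
      for (g in groups) {
        s <- r$group_summaries[[g]]
        row[[paste0("group_", g)]] <- if (is.null(s)) "" else
          sprintf(paste0("%d (%.", dp, "f%%)"), s$counts[li], s$percent[li])
      }
      row$test <- if (li == 1L) r$test$selected else ""
      row$statistic <- if (li == 1L && !is.na(r$statistic))
        formatC(r$statistic, digits = opts$decimals$stat, format = "f") else ""
      row$p <- if (li == 1L) format_p(r$p_value, opts) else ""
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Render a demographic table
#'
#' Continuous rows show `mean (sd) [min-max] n=`; categorical rows show
#' `count (percent)` per level; empty sections are omitted.
#'
#' @param table a `demographic_table`.
#' @param path output path stem (`.csv` / `.md` appended per format).
#' @param opts a [render_options()].
#' @return named character vector of the written file paths, invisibly.
#' @export
render_table1 <- function(table, path, opts = render_options()) {
  df <- table1_frame(table, opts)
  out <- character()
  if ("csv" %in% opts$formats) {
    p <- paste0(path, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    out["csv"] <- p
  }
  if ("markdown" %in% opts$formats) {
    p <- paste0(path, ".md")
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"))
    for (i in seq_len(nrow(df)))
      lines <- c(lines, paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"))
    writeLines(lines, p)
    out["md"] <- p
  }
  invisible(out)
}

km_frame <- function(curves) {
  if (inherits(curves, "km_curve")) curves <- list(all = curves)
  do.call(rbind, lapply(names(curves), function(g) {
    cv <- curves[[g]]
    if (length(cv$event_times) == 0L)
      return(data.frame(time = numeric(), n_risk = numeric(),
                        n_event = numeric(), survival = numeric(),
                        ci_lo = numeric(), ci_hi = numeric(),
                        group = character()))
    data.frame(time = cv$event_times, n_risk = cv$n_at_risk,
               n_event = cv$n_events, survival = cv$survival,
               ci_lo = cv$ci_lower, ci_hi = cv$ci_upper,
               group = g, stringsAsFactors = FALSE)
  }))
}

#' Plot method for Kaplan-Meier curves
#'
#' Right-continuous step functions (survival drops at event times), censor
#' ticks at censored times, optional pointwise confidence band.
#'
#' @param x a `km_curve` or `km_curve_list`.
#' @param conf_band draw the pointwise band.
#' @param col line colours, recycled over groups.
#' @param xlab,ylab,main usual plot labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.km_curve <- function(x, conf_band = TRUE, col = "black",
                          xlab = "Time", ylab = "Survival probability",
                          main = NULL, ...) {
  plot_km_curves(list(x), conf_band = conf_band, col = col, xlab = xlab,
                 ylab = ylab, main = main, ...)
}

#' @rdname plot.km_curve
#' @export
plot.km_curve_list <- function(x, conf_band = FALSE, col = NULL,
                               xlab = "Time", ylab = "Survival probability",
                               main = NULL, ...) {
  plot_km_curves(x, conf_band = conf_band,
                 col = col %||% seq_along(x), xlab = xlab, ylab = ylab,
                 main = main, ...)
}

plot_km_curves <- function(curves, conf_band, col, xlab, ylab, main, ...) {
  xmax <- max(c(unlist(lapply(curves, function(cv)
    c(cv$event_times, cv$censor_times))), 1))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    tx <- c(0, rep(cv$event_times, each = 2))
    sy <- c(1, 1, rep(cv$survival[-length(cv$survival)], each = 2),
            cv$survival[length(cv$survival)])
    if (length(cv$event_times) == 0L) { tx <- c(0, xmax); sy <- c(1, 1) }
    graphics::lines(tx, sy, col = col[i], lwd = 2)
    if (conf_band && length(cv$event_times) > 0L) {
      sfun <- stats::stepfun(cv$event_times, c(1, cv$ci_lower))
      graphics::lines(sfun, col = col[i], lty = 3, do.points = FALSE)
      sfun <- stats::stepfun(cv$event_times, c(1, cv$ci_upper))
      graphics::lines(sfun, col = col[i], lty = 3, do.points = FALSE)
    }
    if (length(cv$censor_times) > 0L) {
      sc <- km_survival_at(cv, cv$censor_times)
      graphics::points(cv$censor_times, sc, pch = 3, cex = 0.7, col = col[i])
    }
  }
  if (length(curves) > 1L && !is.null(names(curves)))
    graphics::legend("topright", legend = names(curves), col = col,
                     lwd = 2, bty = "n", cex = 0.8)
  invisible(NULL)
}

#' Render Kaplan-Meier curves to files
#'
#' Writes the step-function plot (SVG) with censor marks and confidence bands,
#' a companion CSV identical to the curve export, and annotates the log-rank p
#' when a test is supplied. A curve whose median is never reached is
#' summarised as "median not reached".
#'
#' @param curves a `km_curve`, `km_curve_list` or `km_analysis`.
#' @param test optional `logrank_result` (taken from a `km_analysis`
#'   automatically).
#' @param path output path stem.
#' @param opts a [render_options()].
#' @return named character vector of written paths, invisibly.
#' @export
render_km <- function(curves, test = NULL, path, opts = render_options()) {
  if (inherits(curves, "km_analysis")) {
    test <- test %||% curves$logrank
    curves <- curves$curves
  }
  if (inherits(curves, "km_curve"))
    curves <- structure(list(all = curves), class = "km_curve_list")
  out <- character()
  if ("csv" %in% opts$formats) {
    p <- paste0(path, ".csv")
    utils::write.csv(km_frame(curves), p, row.names = FALSE)
    out["csv"] <- p
  }
  if ("plot" %in% opts$formats) {
    p <- paste0(path, ".svg")
    grDevices::svg(p, width = 7, height = 5)
    main <- if (!is.null(test))
      paste0("log-rank p = ", format_p(test$p_value, opts)) else NULL
    plot(curves, main = main)
    grDevices::dev.off()
    out["plot"] <- p
  }
  meds <- vapply(names(curves), function(g) {
    m <- median_survival(curves[[g]])
    paste0(g, ": median ", if (m$reached) format(m$median, digits = 4)
           else "not reached")
  }, "")
  message(paste(meds, collapse = "; "))
  invisible(out)
}
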