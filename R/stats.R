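# Group-comparison statistics and run-level reporting.  The tests delegate
# to the classical routines in stats; this module standardizes their output
# as mean +/- SEM tables.

group_stats <- function(x) {
  c(n = length(x), mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}

comparison <- function(labels, groups, test, statistic, p_value) {
  tab <- do.call(rbind, lapply(groups, group_stats))
  structure(list(groups = data.frame(group = labels, tab,
                                     row.names = NULL),
                 test = test, statistic = statistic, p_value = p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  for (k in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$groups$group[k],
                x$groups$mean[k], x$groups$sem[k], x$groups$n[k]))
  invisible(x)
}

check_variation <- function(groups) {
  if (all(vapply(groups, function(g) stats::sd(g) == 0, logical(1))))
    stop("degenerate test: zero variance in every group")
}

#' Paired and unpaired t tests, one-way ANOVA
#'
#' Thin wrappers around \code{stats::t.test} and
#' \code{stats::oneway.test(var.equal = TRUE)} (classical one-way ANOVA)
#' that return a standardized \code{"group_comparison"} with per-group n,
#' mean and SEM.  All tests are two-sided.
#'
#' @param x,y Numeric samples (equal length for the paired test).
#' @param labels Group labels.
#' @return A \code{"group_comparison"} object.
#' @export
paired_t <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("paired test needs equal-length samples")
  if (length(x) < 2) stop("n >= 2 required per group")
  check_variation(list(x - y))
  tt <- stats::t.test(x, y, paired = TRUE)
  comparison(labels, list(x, y), "paired t-test",
             unname(tt$statistic), tt$p.value)
}

#' @rdname paired_t
#' @export
unpaired_t <- function(x, y, labels = c("x", "y")) {
  if (length(x) < 2 || length(y) < 2) stop("n >= 2 required per group")
  check_variation(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  comparison(labels, list(x, y), "unpaired t-test",
             unname(tt$statistic), tt$p.value)
}

#' @rdname paired_t
#' @param groups Named list of numeric samples (>= 2 groups).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("ANOVA needs at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) stop("n >= 2 required per group")
  check_variation(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  comparison(names(groups), groups, "one-way ANOVA",
             unname(ow$statistic), ow$p.value)
}

#' Tukey multiple-comparison post-hoc
#'
#' Delegates to \code{stats::TukeyHSD} on a one-way \code{aov} fit and
#' reports which group pairs differ at the requested level.
#'
#' @param groups Named list of numeric samples.
#' @param alpha Familywise significance level.
#' @return Data.frame with pair, difference, adjusted p and a
#'   \code{significant} flag.
#' @export
tukey_posthoc <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  th <- stats::TukeyHSD(stats::aov(y ~ g))$g
  data.frame(pair = rownames(th), diff = th[, "diff"],
             p_adj = th[, "p adj"], significant = th[, "p adj"] < alpha,
             row.names = NULL)
}

#' Assemble a run report
#'
#' Collects named analysis tables into one machine-readable structure and a
#' human-readable text summary, echoing configuration and seed so a run can
#' be reproduced.  Regenerating the report from the same inputs is
#' byte-identical.
#'
#' @param tables Named list of data.frames (one per analysis).
#' @param config A [run_config()] (echoed into the report).
#' @return List of class \code{"run_report"}: \code{tables}, \code{config},
#'   \code{text} (character vector of summary lines).
#' @export
make_report <- function(tables = list(), config = run_config()) {
  lines <- c("ampafluct run report",
             sprintf("seed: %d", config$seed),
             sprintf("config: bins=%d min_events=%d rise_cutoff=%g ms threshold=%g",
                     config$n_bins, config$min_events, config$rise_cutoff_ms,
                     config$threshold))
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    lines <- c(lines, sprintf("-- %s (%d row(s)) --", nm, nrow(tab)),
               utils::capture.output(print(tab, row.names = FALSE)))
  }
  if (length(tables) == 0L) lines <- c(lines, "(no analyses)")
  structure(list(tables = tables, config = config, text = lines),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}

#' Write a run report to disk
#'
#' @param report A \code{"run_report"}.
#' @param dir Output directory (created if absent): one CSV per table plus
#'   \code{summary.txt}.
#' @return Invisibly, \code{dir}.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  writeLines(report$text, file.path(dir, "summary.txt"))
  invisible(dir)
}
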