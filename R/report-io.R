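# Serialization of the statistics report: JSON for machines, Markdown
# tables mirroring the demographic / risk-factor / offset-direction layout.

#' Write a statistics report to JSON
#'
#' @param report a "statsReport" from [cohortStats()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStatsJSON <- function(report, path) {
  rec <- list(
    counts = report$counts,
    exclusion_flow = report$exclusionFlow,
    group_comparison = report$groupComparison,
    correlations = report$correlations,
    logistic_univariable = report$logistic$univariable,
    logistic_multivariable = report$logistic$multivariable,
    gee_univariable = report$gee$univariable,
    gee_multivariable = report$gee$multivariable)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.mdTable <- function(d, digits = 3) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(d), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|")
  rows <- apply(d, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

#' Write a statistics report as Markdown tables
#'
#' Emits the exclusion flow, the per-variable group comparison, the
#' correlation summary, and the univariable/multivariable model tables.
#'
#' @param report a "statsReport" from [cohortStats()].
#' @param path output path (.md).
#' @return the path, invisibly.
#' @export
writeStatsMarkdown <- function(report, path) {
  lines <- c("# Cohort statistics",
             "",
             sprintf("%d eyes of %d subjects; %d with eyeball asymmetry.",
                     report$counts$eyes, report$counts$subjects,
                     report$counts$group2),
             "", "## Exclusion flow", "",
             .mdTable(report$exclusionFlow),
             "", "## Group comparison", "",
             .mdTable(report$groupComparison),
             "", "## Correlations (group 2)", "",
             sprintf("- OPP angle vs LC/BMO offset angle: r = %.3f (p = %.3g, n = %d)",
                     report$correlations$opp_vs_offset_angle$r,
                     report$correlations$opp_vs_offset_angle$p,
                     report$correlations$opp_vs_offset_angle$n),
             sprintf("- protrusion depth vs offset index: r = %.3f (p = %.3g, n = %d)",
                     report$correlations$depth_vs_offset_index$r,
                     report$correlations$depth_vs_offset_index$p,
                     report$correlations$depth_vs_offset_index$n),
             "", "## Asymmetry risk factors (random-intercept logistic)", "",
             "### Univariable", "", .mdTable(report$logistic$univariable))
  if (!is.null(report$logistic$multivariable))
    lines <- c(lines, "", "### Multivariable (univariable p < 0.10)", "",
               .mdTable(report$logistic$multivariable))
  lines <- c(lines, "", "## Offset direction (linear GEE)", "",
             "### Univariable", "", .mdTable(report$gee$univariable))
  if (!is.null(report$gee$multivariable))
    lines <- c(lines, "", "### Multivariable (univariable p < 0.10)", "",
               .mdTable(report$gee$multivariable))
  writeLines(lines, path)
  invisible(path)
}
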