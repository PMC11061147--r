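# Cohort-level statistics: exclusion-flow accounting, group comparisons,
# correlations, and random-intercept logistic regression for paired eyes.

.exclusionOrder <- c("no_scan", "withdrew", "metal_fb", "poor_mri",
                     "poor_oct", "crvt_bifurcation")

#' Apply the subject-level exclusion flow
#'
#' Exclusion flags are subject-level: a flag on either eye drops both eyes.
#' Filters are applied in the study order (no_scan, withdrew, metal_fb,
#' poor_mri, poor_oct, crvt_bifurcation); a subject carrying several flags is
#' counted at the first-listed one (and a note is emitted).  The retained set
#' is identical under any permutation of disjoint filters.
#'
#' @param manifest data.frame with one row per eye, a `subject_id` column
#'   and logical flag columns (any subset of the exclusion order).
#' @return list with `retained` (rows of `manifest`) and `flow`
#'   (data.frame: step, subjects_removed, subjects_remaining, eyes_remaining).
#' @export
applyExclusions <- function(manifest) {
  stopifnot("subject_id" %in% names(manifest))
  flags <- intersect(.exclusionOrder, names(manifest))
  subj <- unique(manifest$subject_id)
  subjFlag <- sapply(flags, function(f)
    vapply(subj, function(s)
      any(manifest[[f]][manifest$subject_id == s]), TRUE))
  if (length(flags) == 1L) subjFlag <- matrix(subjFlag, ncol = 1,
                                              dimnames = list(NULL, flags))
  multi <- rowSums(subjFlag) > 1
  if (any(multi))
    message(sum(multi), " subject(s) carry multiple exclusion flags; ",
            "counted at the first-listed exclusion")
  removed <- rep(FALSE, length(subj))
  flow <- data.frame(step = "enrolled", subjects_removed = 0L,
                     subjects_remaining = length(subj),
                     eyes_remaining = nrow(manifest),
                     stringsAsFactors = FALSE)
  for (f in flags) {
    hit <- subjFlag[, f] & !removed
    removed <- removed | hit
    keepRows <- manifest$subject_id %in% subj[!removed]
    flow <- rbind(flow, data.frame(step = f, subjects_removed = sum(hit),
                                   subjects_remaining = sum(!removed),
                                   eyes_remaining = sum(keepRows),
                                   stringsAsFactors = FALSE))
  }
  list(retained = manifest[manifest$subject_id %in% subj[!removed], ],
       flow = flow)
}

#' Compare group 1 and group 2 eyes
#'
#' Independent two-sample t-test for continuous variables (classic
#' equal-variance by default, Welch optionally) and chi-square test for
#' categorical variables; per-group mean +/- SD or counts.
#'
#' @param records data.frame with a `group` column (1/2).
#' @param continuous,categorical variable names.
#' @param welch use the Welch t-test (default FALSE).
#' @return data.frame with per-variable summaries, test statistic and p.
#' @export
compareGroups <- function(records,
                          continuous = c("age", "axial_length", "iop",
                                         "bmo_area", "offset_angle",
                                         "ppa_angle", "offset_index", "rmse"),
                          categorical = c("sex", "glaucoma"),
                          welch = FALSE) {
  stopifnot("group" %in% names(records))
  g1 <- records[records$group == 1L, , drop = FALSE]
  g2 <- records[records$group == 2L, , drop = FALSE]
  if (!nrow(g1) || !nrow(g2)) stop("both groups must be non-empty")
  rows <- list()
  for (v in intersect(continuous, names(records))) {
    x1 <- g1[[v]][is.finite(g1[[v]])]; x2 <- g2[[v]][is.finite(g2[[v]])]
    tt <- tryCatch(t.test(x1, x2, var.equal = !welch),
                   error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v, test = if (welch) "welch-t" else "t",
      group1 = sprintf("%.2f ± %.2f", mean(x1), sd(x1)),
      group2 = sprintf("%.2f ± %.2f", mean(x2), sd(x2)),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      stringsAsFactors = FALSE)
  }
  for (v in intersect(categorical, names(records))) {
    tab <- table(factor(records$group), factor(records[[v]]))
    ct <- tryCatch(suppressWarnings(chisq.test(tab)), error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v, test = "chi-square",
      group1 = paste(table(factor(g1[[v]])), collapse = " / "),
      group2 = paste(table(factor(g2[[v]])), collapse = " / "),
      statistic = if (is.null(ct)) NA_real_ else unname(ct$statistic),
      p = if (is.null(ct)) NA_real_ else ct$p.value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pearson correlation between two per-eye metrics
#'
#' Angles are analyzed as signed degrees (linear scale), matching the
#' correlation of OPP location with LC/BMO offset direction.
#'
#' @param x,y paired numeric vectors (NA pairs dropped).
#' @return list with `r`, `p` and `n`.
#' @export
correlateMetrics <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("at least 3 complete pairs required")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Random-intercept logistic regression for paired eyes
#'
#' Logistic regression with a per-subject random intercept (adaptive
#' Gauss-Hermite quadrature, 7 points) for a binary outcome such as eyeball
#' asymmetry; univariable screen at p < `pEnter`, then a multivariable model
#' with the retained covariates.  Odds ratios with Wald 95% CIs.
#'
#' @param records data.frame with `subject_id`, the outcome column (logical
#'   or 0/1) and candidate columns.
#' @param outcome outcome column name.
#' @param candidates candidate covariate names.
#' @param pEnter screening threshold (default 0.10).
#' @param nAGQ quadrature points (default 7).
#' @return list with `univariable` and `multivariable` tables (term, or,
#'   ci_low, ci_high, p, flagged) — `flagged` marks likely separation.
#' @export
logisticRandomEffects <- function(records, outcome, candidates,
                                  pEnter = 0.10, nAGQ = 7L) {
  stopifnot(outcome %in% names(records), all(candidates %in% names(records)))
  d <- records[stats::complete.cases(records[, c("subject_id", outcome,
                                                 candidates)]), ]
  if (length(unique(d$subject_id)) < 2L)
    stop("at least 2 subjects required for a random-intercept model")
  d$.y <- as.integer(as.logical(d[[outcome]]))
  oneTable <- function(vars) {
    fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + "),
                                   "+ (1 | subject_id)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = d, family = binomial(), nAGQ = nAGQ)))
    co <- summary(fit)$coefficients
    co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
    flagged <- abs(co[, "Estimate"]) > 15 | co[, "Std. Error"] > 15
    data.frame(term = rownames(co), or = exp(co[, "Estimate"]),
               ci_low = exp(co[, "Estimate"] - qnorm(0.975) * co[, "Std. Error"]),
               ci_high = exp(co[, "Estimate"] + qnorm(0.975) * co[, "Std. Error"]),
               p = co[, "Pr(>|z|)"], flagged = flagged,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(candidates, oneTable))
  keepTerms <- unique(uni$term[uni$p < pEnter])
  keep <- candidates[vapply(candidates, function(v)
    any(startsWith(keepTerms, v)), TRUE)]
  multi <- if (length(keep)) oneTable(keep) else NULL
  if (any(uni$flagged))
    warning("possible separation in: ",
            paste(uni$term[uni$flagged], collapse = ", "),
            " (estimates unreliable)")
  list(univariable = uni, multivariable = multi)
}

#' Full statistics stage on a cohort manifest
#'
#' Exclusion flow, group comparison, OPP/offset correlations in group-2
#' eyes, random-effects logistic model of asymmetry, and linear GEE of the
#' offset direction.
#'
#' @param manifest per-eye cohort data.frame (see [makeCohort()]).
#' @param ... passed to [compareGroups()].
#' @return list of class "statsReport": `exclusionFlow`, `groupComparison`,
#'   `correlations`, `logistic`, `gee`, `counts`.
#' @export
cohortStats <- function(manifest, ...) {
  ex <- applyExclusions(manifest)
  d <- ex$retained
  d$asymmetric <- d$group == 2L
  g2 <- d[d$group == 2L, ]
  corrs <- list(
    opp_vs_offset_angle = correlateMetrics(g2$opp_angle, g2$offset_angle),
    depth_vs_offset_index = correlateMetrics(g2$protrusion_depth,
                                             g2$offset_index))
  logit <- logisticRandomEffects(
    d, "asymmetric",
    candidates = c("age", "axial_length", "iop", "bmo_area",
                   "offset_angle", "offset_index"))
  gee <- geeLinear(
    g2, "offset_angle",
    candidates = c("age", "axial_length", "iop", "bmo_area", "opp_angle"))
  out <- list(exclusionFlow = ex$flow,
              groupComparison = compareGroups(d, ...),
              correlations = corrs, logistic = logit, gee = gee,
              counts = list(eyes = nrow(d),
                            subjects = length(unique(d$subject_id)),
                            group2 = sum(d$group == 2L)))
  class(out) <- "statsReport"
  out
}

#' @export
print.statsReport <- function(x, ...) {
  cat("Cohort statistics report\n")
  cat(sprintf("  %d eyes of %d subjects; %d (%.0f%%) with eyeball asymmetry\n",
              x$counts$eyes, x$counts$subjects, x$counts$group2,
              100 * x$counts$group2 / x$counts$eyes))
  cat(sprintf("  OPP angle vs offset angle: r = %.3f (p = %.2g, n = %d)\n",
              x$correlations$opp_vs_offset_angle$r,
              x$correlations$opp_vs_offset_angle$p,
              x$correlations$opp_vs_offset_angle$n))
  cat(sprintf("  depth vs offset index:     r = %.3f (p = %.2g, n = %d)\n",
              x$correlations$depth_vs_offset_index$r,
              x$correlations$depth_vs_offset_index$p,
              x$correlations$depth_vs_offset_index$n))
  invisible(x)
}
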