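# Exclusion flow, group comparisons, correlation, random-effects logistic
# and linear GEE.

paperManifest <- function() {
  n <- 96L
  m <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = sprintf("S%02d", i), eye = c("OD", "OS"),
               withdrew = FALSE, metal_fb = FALSE, poor_mri = FALSE,
               poor_oct = FALSE, crvt_bifurcation = FALSE)))
  flag <- function(m, subjects, col) {
    m[m$subject_id %in% sprintf("S%02d", subjects), col] <- TRUE
    m
  }
  m <- flag(m, 1:3, "withdrew")
  m <- flag(m, 4, "metal_fb")
  m <- flag(m, 5:8, "poor_mri")
  m <- flag(m, 9:10, "poor_oct")
  m <- flag(m, 11, "crvt_bifurcation")
  m
}

test_that("the printed exclusion flow yields 170 eyes of 85 subjects", {
  ex <- applyExclusions(paperManifest())
  expect_equal(nrow(ex$retained), 170L)
  expect_equal(length(unique(ex$retained$subject_id)), 85L)
  expect_equal(ex$flow$subjects_removed,
               c(0L, 3L, 1L, 4L, 2L, 1L))
  expect_equal(ex$flow$eyes_remaining[nrow(ex$flow)], 170L)
})

test_that("exclusion edge cases: none flagged, all flagged, conflicts", {
  m <- paperManifest()
  clean <- m
  clean[, 3:7] <- FALSE
  expect_equal(nrow(applyExclusions(clean)$retained), 192L)
  all_fl <- m
  all_fl$poor_mri <- TRUE
  expect_equal(nrow(applyExclusions(all_fl)$retained), 0L)
  # a subject with two flags is removed once, at the first-listed filter
  both <- clean
  both$withdrew[both$subject_id == "S01"] <- TRUE
  both$poor_oct[both$subject_id == "S01"] <- TRUE
  expect_message(ex <- applyExclusions(both), "multiple")
  expect_equal(ex$flow$subjects_removed[ex$flow$step == "withdrew"], 1L)
  expect_equal(ex$flow$subjects_removed[ex$flow$step == "poor_oct"], 0L)
})

test_that("exclusion flow is order-independent for disjoint flags", {
  m <- paperManifest()
  shuffled <- m[, c("subject_id", "eye", "crvt_bifurcation", "poor_oct",
                    "poor_mri", "metal_fb", "withdrew")]
  expect_equal(sort(unique(applyExclusions(m)$retained$subject_id)),
               sort(unique(applyExclusions(shuffled)$retained$subject_id)))
})

test_that("group comparison runs t and chi-square tests with summaries", {
  co <- makeCohort(seed = 2L)
  tab <- compareGroups(applyExclusions(co$manifest)$retained)
  expect_true(all(c("offset_index", "rmse", "sex") %in% tab$variable))
  # the generator builds group 2 with a larger offset index and rmse
  expect_lt(tab$p[tab$variable == "rmse"], 0.05)
  expect_equal(tab$test[tab$variable == "sex"], "chi-square")
  # identical constant samples leave the t statistic undefined
  cons <- data.frame(group = rep(1:2, each = 10), age = 5)
  expect_true(is.na(compareGroups(cons, continuous = "age",
                                  categorical = character())$p))
  expect_error(compareGroups(data.frame(group = 1, age = 1)), "non-empty")
})

test_that("a strong mean shift is detected with near-certain power", {
  set.seed(14)
  d <- data.frame(group = rep(1:2, each = 80),
                  age = c(rnorm(80, 0), rnorm(80, 1)))
  expect_lt(compareGroups(d, continuous = "age",
                          categorical = character())$p, 1e-4)
})

test_that("correlation treats angles as signed degrees", {
  x <- c(-120, -60, 0, 45, 170)
  expect_equal(correlateMetrics(x, -x)$r, -1)
  expect_error(correlateMetrics(1:2, 2:1), "3")
})

test_that("random-effects logistic recovers a strong odds ratio", {
  set.seed(70)
  ns <- 200L
  b <- rnorm(ns, 0, 1)
  d <- data.frame(subject_id = rep(seq_len(ns), each = 2))
  d$x <- rnorm(2 * ns)
  d$noisevar <- rnorm(2 * ns)
  d$y <- rbinom(2 * ns, 1, plogis(log(3) * d$x + b[d$subject_id]))
  fit <- logisticRandomEffects(d, "y", c("x", "noisevar"))
  or <- fit$univariable$or[fit$univariable$term == "x"]
  expect_gt(or, 2); expect_lt(or, 4.5)
  # screening keeps the real covariate in the multivariable model
  expect_true("x" %in% fit$multivariable$term)
  expect_error(logisticRandomEffects(d[d$subject_id == 1, ], "y", "x"),
               "2 subjects")
})

test_that("GEE with one eye per subject equals ordinary least squares", {
  set.seed(8)
  d <- data.frame(subject_id = 1:60, x = rnorm(60))
  d$offset_angle <- 3 - 2 * d$x + rnorm(60, 0, 5)
  gee <- geeLinear(d, "offset_angle", "x")
  ols <- lm(offset_angle ~ x, data = d)
  expect_equal(unname(gee$model$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("stats report serializes to JSON and Markdown", {
  co <- makeCohort(seed = 31L)
  rep <- cohortStats(co$manifest)
  fj <- tempfile(fileext = ".json")
  writeStatsJSON(rep, fj)
  back <- jsonlite::fromJSON(fj)
  expect_equal(back$counts$eyes, rep$counts$eyes)
  expect_equal(back$correlations$opp_vs_offset_angle$r,
               rep$correlations$opp_vs_offset_angle$r, tolerance = 1e-12)
  fm <- tempfile(fileext = ".md")
  writeStatsMarkdown(rep, fm)
  md <- readLines(fm)
  expect_true(any(grepl("Exclusion flow", md)))
  expect_true(any(grepl("opp_angle", md)))
  unlink(c(fj, fm))
})

test_that("GEE recovers an injected paired-eye slope", {
  set.seed(15)
  ns <- 85L
  b <- rnorm(ns, 0, 25)
  d <- data.frame(subject_id = rep(seq_len(ns), each = 2))
  d$opp_angle <- wrapAngle(rnorm(2 * ns, -68, 51))
  d$junk <- rnorm(2 * ns)
  d$offset_angle <- 12.6 - 0.38 * d$opp_angle + b[d$subject_id] +
    rnorm(2 * ns, 0, 30)
  fit <- geeLinear(d, "offset_angle", c("opp_angle", "junk"))
  est <- fit$univariable$estimate[fit$univariable$term == "opp_angle"]
  expect_lt(abs(est + 0.38), 0.1)
  expect_true("opp_angle" %in% fit$multivariable$term)
  # exchangeable correlation was actually estimated
  expect_gt(fit$model$alpha, 0.1)
})
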