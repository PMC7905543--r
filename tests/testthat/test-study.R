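dev <- function(tfs, tfa) list(tfs = tfs, tfa = tfa)

toy_raters <- function() {
  rater_table(data.frame(
    rater_id = c("g", "b1", "b2", "s1", "s2", "s3", "j1", "j2", "j3"),
    profession = c("SS", "BE", "BE", "SOR", "SOR", "SOR", "JOR", "JOR", "JOR"),
    clinical_years = c(24, NA, NA, 6, 6, 7, 1.5, 3, 1.5),
    planning_years = c(10, 2, 3, 1.5, 1, 0, 0, 0, 0)))
}

# deviation table with per-rater case means equal to `means` + small jitter
toy_devdf <- function(means, n_cases = 4, jitter = 0.1) {
  rows <- list()
  for (r in names(means)) {
    for (ci in seq_len(n_cases)) {
      val <- means[[r]] + jitter * (ci - (n_cases + 1) / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = r, case_id = sprintf("c%d", ci),
        tfs = val, tfa = 2 * val, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("case aggregation is the arithmetic mean over fragments", {
  cs <- aggregate_case(list(dev(2, 10), dev(4, 20)), "r", "c")
  expect_equal(cs$mean_tfs, 3); expect_equal(cs$mean_tfa, 15)
  expect_equal(cs$n_fragments, 2)
  single <- aggregate_case(list(dev(1.5, 5)))
  expect_equal(single$mean_tfs, 1.5); expect_equal(single$mean_tfa, 5)
  set.seed(61)
  tfs <- runif(20, 0, 8); tfa <- runif(20, 0, 30)
  many <- aggregate_case(mapply(dev, tfs, tfa, SIMPLIFY = FALSE))
  expect_equal(many$mean_tfs, sum(tfs) / 20, tolerance = 1e-12)
  expect_equal(many$mean_tfa, sum(tfa) / 20, tolerance = 1e-12)
  expect_error(aggregate_case(list()), "no fragment")
})

test_that("rater aggregation uses the n-1 standard deviation over case means", {
  mk <- function(v) lapply(seq_along(v), function(i) {
    list(rater_id = "r", case_id = i, mean_tfs = v[i], mean_tfa = v[i])
  })
  rs <- aggregate_rater(mk(c(1, 3)))
  expect_equal(rs$mean_tfs, 2); expect_equal(rs$sd_tfs, sqrt(2))
  rs <- aggregate_rater(mk(rep(2.5, 20)))
  expect_equal(rs$mean_tfs, 2.5); expect_equal(rs$sd_tfs, 0)
  set.seed(62)
  v <- rnorm(20, 5)
  rs <- aggregate_rater(mk(v))
  # two-pass variance oracle
  m <- sum(v) / 20
  expect_equal(rs$sd_tfs, sqrt(sum((v - m)^2) / 19), tolerance = 1e-12)
  expect_error(aggregate_rater(mk(1)), "at least 2")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  a <- oneway_anova(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(a$F, 8)               # SSB 4 (df 1) over SSW 1 (df 2)
  expect_equal(a$df_between, 1); expect_equal(a$df_within, 2)
  expect_equal(a$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(oneway_anova(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))$F, 0)
  # textbook formula oracle on unbalanced 2/3/3 groups
  set.seed(63)
  vals <- rnorm(8, mean = rep(c(0, 1, 3), c(2, 3, 3)))
  grp <- rep(c("BE", "SOR", "JOR"), c(2, 3, 3))
  a <- oneway_anova(vals, grp)
  gm <- tapply(vals, grp, mean); gn <- tapply(vals, grp, length)
  ssb <- sum(gn * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  expect_equal(a$F, (ssb / 2) / (ssw / 5), tolerance = 1e-10)
  expect_equal(a$df_between, 2); expect_equal(a$df_within, 5)
  expect_error(oneway_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "degenerate-variance")
  expect_error(oneway_anova(1:4, rep("a", 4)), "2 groups")
})

test_that("Bonferroni post hoc multiplies pooled-t p-values by the pair count, capped", {
  set.seed(64)
  vals <- c(rnorm(2), rnorm(3, 1), rnorm(3, 4))
  grp <- rep(c("BE", "SOR", "JOR"), c(2, 3, 3))
  ph <- bonferroni_posthoc(vals, grp)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
  # pooled two-sample t oracle per pair
  for (i in seq_len(3)) {
    x <- vals[grp == ph$group1[i]]; y <- vals[grp == ph$group2[i]]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(ph$t[i], tstat, tolerance = 1e-10)
    expect_equal(ph$p_raw[i], 2 * pt(-abs(tstat), n1 + n2 - 2), tolerance = 1e-10)
  }
  # cap at 1
  near <- c(1.0, 1.1, 1.05, 1.02, 1.08, 0.98, 1.01, 1.07)
  ph2 <- bonferroni_posthoc(near, grp)
  expect_true(any(ph2$p_adj == 1))
  expect_error(bonferroni_posthoc(c(1, 2), c("a", "b")), "insufficient")
})

test_that("experience regression matches the normal-equations oracle", {
  # perfect line (summary.lm warns about the exact fit; the numbers are exact)
  r <- suppressWarnings(regress_experience(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r <- regress_experience(c(0, 1, 2, 3), c(2, 2, 2, 2))
  expect_equal(r$slope, 0); expect_equal(r$r_squared, 0)
  set.seed(65)
  x <- runif(8, 0, 10); y <- 5 - 0.6 * x + rnorm(8, sd = 0.5)
  r <- regress_experience(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(r$r_squared, r2, tolerance = 1e-10)
  tstat <- beta[2] / sqrt(sum(res^2) / 6 / sum((x - mean(x))^2))
  expect_equal(r$F, tstat^2, tolerance = 1e-8)
  expect_equal(r$improvement_per_year, -beta[2], tolerance = 1e-10)
  # NA experience values shrink the fit, not crash it
  r <- regress_experience(c(NA, NA, x[3:8]), y)
  expect_equal(r$n, 6)
  expect_error(regress_experience(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("group ANOVA within the pipeline equals the hand computation", {
  means <- list(b1 = 1, b2 = 2, s1 = 1.5, s2 = 2.5, s3 = 2, j1 = 5, j2 = 6, j3 = 5.5)
  res <- analyze_deviations(toy_devdf(means), toy_raters(), gold = "g")
  rmeans <- res$rater_summaries$mean_tfs
  grp <- res$rater_summaries$profession
  gm <- tapply(rmeans, grp, mean); gn <- tapply(rmeans, grp, length)
  ssb <- sum(gn * (gm - mean(rmeans))^2)
  ssw <- sum((rmeans - gm[grp])^2)
  expect_equal(res$anova$tfs_mean$F, (ssb / 2) / (ssw / 5), tolerance = 1e-10)
  # regression dfs: planning over all 8, clinical over the 6 residents
  expect_equal(res$regressions$tfs_planning$df2, 6)
  expect_equal(res$regressions$tfs_clinical$df2, 4)
  expect_equal(res$regressions$tfs_clinical$n, 6)
})

test_that("a study with zero deviations reports no variability instead of failing", {
  set.seed(66)
  cs <- generate_case(660, 2)
  raters <- toy_raters()
  rows <- list(); poses <- list()
  for (r in raters$rater_id) {
    for (fid in names(cs$meshes)) {
      rows[[length(rows) + 1L]] <- data.frame(rater_id = r, case_id = "c1",
                                              fragment_id = fid,
                                              stringsAsFactors = FALSE)
      poses[[length(poses) + 1L]] <- cs$gold_poses[[fid]]
    }
    # second case so per-rater sd is defined
    for (fid in names(cs$meshes)) {
      rows[[length(rows) + 1L]] <- data.frame(rater_id = r, case_id = "c2",
                                              fragment_id = fid,
                                              stringsAsFactors = FALSE)
      poses[[length(poses) + 1L]] <- cs$gold_poses[[fid]]
    }
  }
  df <- do.call(rbind, rows); df$pose <- poses
  meshes <- list()
  for (fid in names(cs$meshes)) {
    meshes[[mesh_key("c1", fid)]] <- cs$meshes[[fid]]
    meshes[[mesh_key("c2", fid)]] <- cs$meshes[[fid]]
  }
  res <- run_study(plan_table(df, "g"), raters, meshes)
  expect_true(all(res$rater_summaries$mean_tfs == 0))
  expect_true(all(res$rater_summaries$sd_tfa == 0))
  expect_match(res$anova, "no variability")
})

test_that("scaling all deviations scales summaries but leaves F, R2 and p fixed", {
  means <- list(b1 = 1, b2 = 2, s1 = 1.5, s2 = 2.5, s3 = 2, j1 = 5, j2 = 6, j3 = 5.5)
  d1 <- toy_devdf(means)
  d2 <- d1; d2$tfs <- 3 * d2$tfs; d2$tfa <- 3 * d2$tfa
  r1 <- analyze_deviations(d1, toy_raters(), gold = "g")
  r2 <- analyze_deviations(d2, toy_raters(), gold = "g")
  expect_equal(r2$rater_summaries$mean_tfs, 3 * r1$rater_summaries$mean_tfs,
               tolerance = 1e-12)
  expect_equal(r2$rater_summaries$sd_tfa, 3 * r1$rater_summaries$sd_tfa,
               tolerance = 1e-12)
  expect_equal(r2$anova$tfs_mean$F, r1$anova$tfs_mean$F, tolerance = 1e-10)
  expect_equal(r2$anova$tfa_mean$p, r1$anova$tfa_mean$p, tolerance = 1e-10)
  expect_equal(r2$regressions$tfs_planning$r_squared,
               r1$regressions$tfs_planning$r_squared, tolerance = 1e-10)
  expect_equal(r2$regressions$tfs_planning$p,
               r1$regressions$tfs_planning$p, tolerance = 1e-10)
  expect_equal(r2$regressions$tfs_planning$slope,
               3 * r1$regressions$tfs_planning$slope, tolerance = 1e-10)
})

test_that("row order of the deviation table never changes any output", {
  means <- list(b1 = 1, b2 = 2, s1 = 1.5, s2 = 2.5, s3 = 2, j1 = 5, j2 = 6, j3 = 5.5)
  d1 <- toy_devdf(means)
  set.seed(67)
  d2 <- d1[sample(nrow(d1)), ]
  r1 <- analyze_deviations(d1, toy_raters(), gold = "g")
  r2 <- analyze_deviations(d2, toy_raters(), gold = "g")
  expect_equal(r1$rater_summaries, r2$rater_summaries, tolerance = 1e-12)
  expect_equal(r1$anova, r2$anova, tolerance = 1e-12)
  expect_equal(r1$regressions, r2$regressions, tolerance = 1e-12)
})

test_that("ANOVA p-values are uniform for exchangeable group data", {
  set.seed(68)
  grp <- rep(c("BE", "SOR", "JOR"), c(2, 3, 3))
  pvals <- replicate(1000, oneway_anova(rnorm(8), sample(grp))$p)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
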