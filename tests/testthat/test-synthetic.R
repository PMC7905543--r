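test_that("packaged demographics reproduce the study case material", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 20)
  expect_equal(count_included_fragments(t1), 51)
  expect_equal(mean_fragments(t1, "included"), 2.55)
  expect_equal(mean_fragments(t1, "total"), 3.15)
  ao <- table(t1$ao_class)
  expect_equal(as.vector(ao[c("2R3A", "2R3B", "2R3C")]), c(2L, 4L, 14L))
  expect_equal(as.vector(table(t1$sex)[c("m", "f")]), c(10L, 10L))
  expect_equal(as.vector(table(t1$side)[c("R", "L")]), c(10L, 10L))
  expect_error(mean_fragments(t1[, -5], "total"), "schema")
  expect_error(count_included_fragments(t1[, -6]), "schema")
})

test_that("packaged rater panel matches the study overview", {
  t2 <- table2_fixture()
  expect_equal(nrow(t2), 9)
  ss <- t2[t2$profession == "SS", ]
  expect_equal(ss$rater_id, "1")
  expect_equal(ss$clinical_years, 24)
  expect_equal(ss$planning_years, 10)
  expect_true(all(is.na(t2$clinical_years[t2$profession == "BE"])))
  expect_equal(sort(t2$planning_years[t2$profession == "BE"]), c(2, 3))
  expect_true(all(t2$planning_years[t2$profession == "JOR"] == 0))
})

test_that("case generation is deterministic and validates the fragment count", {
  c1 <- generate_case(7, 3)
  c2 <- generate_case(7, 3)
  expect_identical(c1, c2)
  expect_length(c1$meshes, 3)
  expect_length(c1$gold_poses, 3)
  expect_length(c1$initial_poses, 3)
  single <- generate_case(8, 1)
  d <- measure_displacement(single$meshes$f1, single$gold_poses$f1,
                            single$initial_poses$f1)
  expect_gt(d$tfs, 0)
  expect_gt(d$tfa, 0)
  expect_error(generate_case(9, 7), "between 1 and 6")
  expect_error(generate_case(9, 0), "between 1 and 6")
})

test_that("noiseless zero-slope model displaces every fragment by exactly its baselines", {
  model <- rater_error_model(tfs_baseline = 2, tfs_slope_planning = 0,
                             tfs_slope_clinical = 0, tfa_baseline = 5,
                             tfa_slope_planning = 0, tfa_slope_clinical = 0,
                             noise_sd_tfs = 0, noise_sd_tfa = 0, seed = 70)
  cs <- generate_case(70, 2)
  prof <- table2_fixture()[5, ]
  plan <- simulate_rater_plan(cs, prof, model, seed = 700)
  for (fid in names(plan)) {
    d <- deviation_from_gold(cs$meshes[[fid]], plan[[fid]], cs$gold_poses[[fid]])
    expect_equal(d$tfs, 2, tolerance = 1e-9)
    expect_equal(d$tfa, 5, tolerance = 1e-9)
  }
})

test_that("enough experience truncates the expected deviation to zero", {
  model <- rater_error_model(noise_sd_tfs = 0, noise_sd_tfa = 0, seed = 71)
  veteran <- data.frame(rater_id = "v", profession = "SOR",
                        clinical_years = 40, planning_years = 40)
  mu <- expected_deviation(model, veteran)
  expect_equal(mu$mu_tfs, 0)
  expect_equal(mu$mu_tfa, 0)
  cs <- generate_case(71, 1)
  plan <- simulate_rater_plan(cs, veteran, model, seed = 710)
  d <- deviation_from_gold(cs$meshes$f1, plan$f1, cs$gold_poses$f1)
  expect_equal(d$tfs, 0, tolerance = 1e-9)
  expect_equal(d$tfa, 0, tolerance = 1e-9)
})

test_that("expected deviations are non-increasing in either experience variable", {
  model <- rater_error_model(seed = 72)
  py <- seq(0, 10, by = 1)
  mus_p <- vapply(py, function(p) {
    expected_deviation(model, list(planning_years = p, clinical_years = 3))$mu_tfs
  }, numeric(1))
  expect_true(all(diff(mus_p) <= 1e-12))
  cy <- seq(0, 24, by = 2)
  mus_c <- vapply(cy, function(cl) {
    expected_deviation(model, list(planning_years = 1, clinical_years = cl))$mu_tfa
  }, numeric(1))
  expect_true(all(diff(mus_c) <= 1e-12))
})

test_that("slope calibration makes the panel's univariate OLS slopes exact", {
  model <- rater_error_model(seed = 73)
  panel <- table2_fixture()
  p <- panel[panel$profession != "SS", ]
  mu <- vapply(seq_len(nrow(p)), function(i) {
    expected_deviation(model, p[i, ])$mu_tfs
  }, numeric(1))
  expect_true(all(mu > 0))  # defaults keep the panel in the linear regime
  # univariate planning slope over all 8 non-gold raters
  fit_p <- lm(mu ~ p$planning_years)
  expect_equal(unname(coef(fit_p)[2]), -0.943, tolerance = 1e-9)
  # univariate clinical slope over the 6 raters possessing clinical years
  keep <- !is.na(p$clinical_years)
  fit_c <- lm(mu[keep] ~ p$clinical_years[keep])
  expect_equal(unname(coef(fit_c)[2]), -0.560, tolerance = 1e-9)
  # same for the angle model
  mua <- vapply(seq_len(nrow(p)), function(i) {
    expected_deviation(model, p[i, ])$mu_tfa
  }, numeric(1))
  expect_equal(unname(coef(lm(mua ~ p$planning_years))[2]), -2.472,
               tolerance = 1e-9)
  expect_equal(unname(coef(lm(mua[keep] ~ p$clinical_years[keep]))[2]), -1.394,
               tolerance = 1e-9)
})

test_that("generated fragment counts follow the configured distribution", {
  probs <- tabulate(table1_fixture()$included_fragments, nbins = 6) / 20
  # fragment counts drawn by many small simulated studies (tiny case count to
  # keep geometry cheap; the draw happens before any mesh is built)
  draws <- integer(0)
  for (s in 1:30) {
    model <- rater_error_model(seed = 7400 + s)
    sim <- simulate_study(model, n_cases = 4,
                          raters = table2_fixture()[1:4, ])
    draws <- c(draws, vapply(sim$cases, function(cs) length(cs$meshes), integer(1)))
  }
  obs <- tabulate(draws, nbins = 6)
  chi <- suppressWarnings(chisq.test(obs[probs > 0], p = probs[probs > 0]))
  expect_gt(chi$p.value, 0.01)
})

test_that("a simulated study is deterministic and orders groups as constructed", {
  model <- rater_error_model(seed = 1)
  sim <- simulate_study(model, n_cases = 6)
  sim2 <- simulate_study(model, n_cases = 6)
  expect_identical(sim$plans$pose, sim2$plans$pose)
  res <- analyze_simulated_study(sim)
  gmeans <- tapply(res$rater_summaries$mean_tfs, res$rater_summaries$profession, mean)
  expect_gt(gmeans[["JOR"]], gmeans[["SOR"]])
  expect_gt(gmeans[["JOR"]], gmeans[["BE"]])
  # every rater in the plan has the gold rows available
  expect_equal(plan_gold(sim$plans), "1")
})

test_that("a simulated study written to disk is consumable by the file pipeline", {
  model <- rater_error_model(seed = 75)
  sim <- simulate_study(model, n_cases = 2, fragment_counts = c(1, 2))
  dir <- withr::local_tempdir()
  write_study_dir(sim, dir)
  plans <- read_plan_table(file.path(dir, "plans.csv"), gold = "1")
  raters <- read_rater_table(file.path(dir, "raters.csv"))
  mesh_map <- read.csv(file.path(dir, "meshes.csv"), stringsAsFactors = FALSE)
  meshes <- list()
  for (i in seq_len(nrow(mesh_map))) {
    meshes[[mesh_key(mesh_map$case_id[i], mesh_map$fragment_id[i])]] <-
      read_mesh(file.path(dir, mesh_map$mesh_path[i]))
  }
  res_disk <- run_study(plans, raters, meshes, pose_dir = dir)
  res_mem <- analyze_simulated_study(sim)
  expect_equal(res_disk$rater_summaries$mean_tfs,
               res_mem$rater_summaries$mean_tfs, tolerance = 1e-6)
  expect_equal(res_disk$rater_summaries$mean_tfa,
               res_mem$rater_summaries$mean_tfa, tolerance = 1e-6)
})
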