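test_that("growth ANOVA separates shifted groups and not identical ones", {
  cfg <- tiny_config(tiny_design(sample_days = 10))
  tab <- rbind(make_table("C", 10, 4, 1.5, 0.9),
               make_table("E", 10, 4, 5, 1.4))
  # identical within group, large shift between groups
  tab$shell_length_cm <- ifelse(tab$group == "E", 9.001, 5.001)
  tab$shell_length_cm <- tab$shell_length_cm + rep_len(c(-0.001, 0.001), nrow(tab))
  # no between-group difference in weight (tiny within-group spread so the
  # residual variance is nonzero)
  tab$dry_weight_g <- 1 + rep_len(c(-0.001, 0.001), nrow(tab))
  cmp <- compare_growth(tab)
  shell <- cmp[cmp$variable == "shell_length", ]
  expect_true(shell$significant)
  expect_match(shell$letters, "C=a")
  expect_match(shell$letters, "E=b")
  weight <- cmp[cmp$variable == "dry_weight", ]
  expect_false(weight$significant)
  expect_match(weight$letters, "C=a.*E=a")

  expect_error(compare_growth(make_table("C", 10, 4, 1.5, 0.9)),
               class = "insufficient_data_error")
})

test_that("importance comparison: strong separation, null case, symmetry", {
  withr::with_seed(21, {
    jit <- rnorm(9, 0, 0.5)
    cells <- do.call(rbind, lapply(jit, function(e)
      apportion_cell(9.16 + e / 10, 0.84 - e / 10)))
  })
  cmp <- compare_importance(cells)
  expect_true(cmp$significant)
  expect_gt(cmp$mean_difference, 80)

  # exact 50/50 cells: zero difference, not significant
  null_cells <- rbind(apportion_cell(5, 5), apportion_cell(2, 2),
                      apportion_cell(1, 1))
  cmp0 <- compare_importance(null_cells)
  expect_false(cmp0$significant)
  expect_equal(cmp0$mean_difference, 0)

  expect_error(compare_importance(apportion_cell(91.6, 8.4)),
               class = "insufficient_data_error")

  # symmetry: swapping routes flips the statistic, p unchanged
  swapped <- cells
  swapped$frac_waterborne <- cells$frac_dietary
  swapped$frac_dietary <- cells$frac_waterborne
  cmp_s <- compare_importance(swapped)
  expect_equal(cmp_s$statistic, -cmp$statistic, tolerance = 1e-12)
  expect_equal(cmp_s$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("run_analysis assembles a complete, deterministic report", {
  sc <- anodonta_scenario(noise_cv = 0.05)
  tab <- simulate_experiment(sc$config, sc$truth, seed = 6)
  rep1 <- run_analysis(tab, sc$config, bootstrap_reps = 100, seed = 2)

  expect_s3_class(rep1, "dualtracer_report")
  expect_equal(rep1$settings$dietary_scaling_factor, 8)
  expect_named(rep1, c("settings", "backgrounds", "new_accumulation",
                       "influx", "apportionment", "comparisons"))
  expect_equal(rep1$apportionment$summary$mean_w +
                 rep1$apportionment$summary$mean_d, 100, tolerance = 1e-9)
  expect_true(is.numeric(rep1$influx$fold_w_over_d))
  expect_equal(nrow(rep1$comparisons$growth), 6L)  # 2 variables x 3 days
  expect_true(rep1$comparisons$importance$significant)
  expect_true(rep1$apportionment$bootstrap_ci$low <=
                rep1$apportionment$bootstrap_ci$high)

  # byte-identical JSON on rerun (no timestamps)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, p1)
  write_report_json(run_analysis(tab, sc$config, bootstrap_reps = 100,
                                 seed = 2), p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_equal(parsed$settings$dietary_scaling_factor, 8)
  expect_true(!is.null(parsed$backgrounds$waterborne$mean))
})

test_that("build_report refuses missing stage outputs", {
  expect_error(build_report(config = NULL), class = "dependency_error")
})

test_that("command-line front end runs end to end", {
  cli <- system.file("cli", "dualtrace.R", package = "dualtracer")
  cfg <- system.file("extdata", "config.yaml", package = "dualtracer")
  truth <- system.file("extdata", "truth.yaml", package = "dualtracer")
  dir <- withr::local_tempdir()
  meas <- file.path(dir, "measurements.csv")
  rscript <- file.path(R.home("bin"), "Rscript")
  lib <- dirname(find.package("dualtracer"))
  env <- sprintf("R_LIBS=%s:%s", lib, paste(.libPaths(), collapse = ":"))
  out1 <- system2(rscript, c(cli, "simulate", "--config", cfg, "--truth", truth,
                             "--seed", "4", "--out", meas),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(meas))
  report <- file.path(dir, "report.json")
  out2 <- system2(rscript, c(cli, "analyze", "--config", cfg,
                             "--measurements", meas, "--out", report),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(report))
  parsed <- jsonlite::read_json(report)
  expect_equal(parsed$settings$dietary_scaling_factor, 8)
})
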