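test_that("tracer_spec and exposure_design enforce their invariants", {
  expect_s3_class(tracer_spec("Cd112", "waterborne", 0.2413, 0.987),
                  "tracer_spec")
  expect_error(tracer_spec("Cd112", "waterborne", 1.2), class = "domain_error")
  expect_error(tracer_spec("Cd112", "waterborne", 0.24, spike_purity = 0),
               class = "domain_error")

  g <- data.frame(name = c("C", "E"), waterborne_conc = c(0, 5),
                  dietary_conc = c(0.5, 2))
  expect_error(exposure_design(g, 1, 10, 3, c(10, 5, 30), 3),
               class = "validation_error")       # non-increasing days
  expect_error(exposure_design(g, 1, 10, 3, c(10, 20), 25),
               class = "domain_error")           # feeding window > day
  g2 <- g; g2$waterborne_conc <- c(1, 5)
  expect_error(exposure_design(g2, 1, 10, 3, c(10, 20), 3),
               class = "validation_error")       # no control group
  d <- tiny_design()
  expect_identical(control_group(d), "C")
})

test_that("analysis_config rejects mismatched tracer routes", {
  w <- tracer_spec("Cd112", "waterborne", 0.2413)
  expect_error(analysis_config(w, w, tiny_design()),
               class = "validation_error")
  cfg <- tiny_config()
  expect_false(cfg$regression_through_origin)
  expect_equal(cfg$qc_tolerance, 0.10)
})

test_that("measurement validation names every malformed input", {
  cfg <- tiny_config()
  good <- make_table(c("C", "E"), c(10, 20, 30), 3, 1.5, 0.9)
  expect_s3_class(validate_measurements(good, cfg$design), "measurement_table")

  bad <- good; bad$conc_w[4] <- -0.1
  expect_error(validate_measurements(bad, cfg$design),
               class = "validation_error")
  bad <- good; bad$day[1] <- 15
  expect_error(validate_measurements(bad, cfg$design), "15",
               class = "validation_error")
  bad <- good; bad$group[2] <- "X"
  expect_error(validate_measurements(bad, cfg$design), "X",
               class = "validation_error")
  bad <- good; bad$mussel_id[2] <- bad$mussel_id[1]
  expect_error(validate_measurements(bad, cfg$design), "duplicate",
               class = "validation_error")
  expect_error(validate_measurements(good[, -5], cfg$design),
               class = "schema_error")
})

test_that("measurement CSV I/O round-trips losslessly", {
  cfg <- tiny_config()
  tab <- make_table(c("C", "E"), c(10, 20, 30), 3,
                    conc_w = c(1.5, pi, 1 / 3, 2.25, sqrt(2), 10.8),
                    conc_d = c(0.9, exp(1), 0.87, 1.37, 5, 6.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path, cfg)
  back <- read_measurements(path, cfg)
  expect_identical(back$conc_w, tab$conc_w)   # bit-exact
  expect_identical(back$conc_d, tab$conc_d)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # header line names the tracer isotopes
  hdr <- readLines(path, n = 1L)
  expect_match(hdr, "cd112_ugg_dw")
  expect_match(hdr, "cd113_ugg_dw")

  # empty table round-trips to an empty table
  write_measurements(tab[0, ], path, cfg)
  expect_identical(nrow(read_measurements(path, cfg)), 0L)

  # missing columns in the file are a schema error
  writeLines("group,day,tank,mussel_id,cd112_ugg_dw", path)
  expect_error(read_measurements(path, cfg), class = "schema_error")
})

test_that("full-design table has one data line per stocked animal", {
  sc <- anodonta_scenario()
  d <- sc$config$design
  # all stocked animals measured once: groups x tanks x animals-per-tank
  n_total <- nrow(d$groups) * d$tanks_per_group * d$mussels_per_tank
  expect_equal(n_total, 180)
  per_day <- d$tanks_per_group * d$mussels_per_tank / length(d$sample_days)
  tab <- make_table(d$groups$name, d$sample_days, per_day, 1.5, 0.9)
  expect_equal(nrow(tab), 180)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path, sc$config)
  expect_length(readLines(path), 181L)  # header + 180 data lines
})

test_that("YAML config round-trips through read/write", {
  sc <- anodonta_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_analysis_config(sc$config, path)
  back <- read_analysis_config(path)
  expect_equal(back, sc$config)

  tpath <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_truth(sc$truth, tpath)
  expect_equal(read_simulation_truth(tpath), sc$truth)
})

test_that("shipped example config parses to the default scenario design", {
  path <- system.file("extdata", "config.yaml", package = "dualtracer")
  cfg <- read_analysis_config(path)
  expect_equal(cfg$design, anodonta_scenario()$config$design)
  expect_equal(cfg$tracers$waterborne$natural_abundance, 0.2413)
  truth <- read_simulation_truth(system.file("extdata", "truth.yaml",
                                             package = "dualtracer"))
  expect_equal(truth$influx_w[["T3"]], 1.25)
})
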