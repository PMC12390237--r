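test_that("background estimation pools the control group", {
  cfg <- tiny_config(tiny_design(sample_days = c(10, 20, 30)))
  tab <- make_table("C", c(10, 20, 30), 1,
                    conc_w = c(1.45, 1.52, 1.59), conc_d = c(0.83, 0.87, 0.91))
  tab <- rbind(tab, make_table("E", 10, 1, 5, 1.37))
  bg <- estimate_background(tab, cfg, "waterborne")
  expect_equal(bg$mean, 1.52)
  expect_equal(bg$n, 3L)
  expect_equal(unname(bg$per_day), c(1.45, 1.52, 1.59))
  bg_d <- estimate_background(tab, cfg, "dietary")
  expect_equal(bg_d$mean, 0.87)

  # single control value: sd 0
  one <- rbind(make_table("C", 10, 1, 1.5, 0.9), make_table("E", 10, 1, 5, 2))
  expect_equal(estimate_background(one, cfg, "waterborne")$sd, 0)

  # control group absent
  expect_error(estimate_background(make_table("E", 10, 2, 5, 2), cfg),
               class = "missing_control_error")
})

test_that("dietary scaling factor is day_hours / feeding_hours", {
  expect_equal(dietary_scaling_factor(3, 24), 8)
  expect_equal(dietary_scaling_factor(24, 24), 1)
  expect_equal(dietary_scaling_factor(6, 24), 4)
  expect_error(dietary_scaling_factor(0, 24), class = "domain_error")
  expect_error(dietary_scaling_factor(25, 24), class = "domain_error")
})

test_that("new accumulation subtracts background and scales dietary by S", {
  cfg <- tiny_config()
  tab <- rbind(make_table("C", c(10, 20, 30), 2, 1.52, 0.87),
               make_table("E", c(10, 20, 30), 2, 5.00, 1.37))
  na <- compute_new_accumulation(tab, cfg)
  expect_s3_class(na, "new_accumulation")
  expect_equal(attr(na, "scaling_factor"), 8)
  expect_equal(unique(na$value[na$route == "waterborne"]), 5.00 - 1.52)
  expect_equal(unique(na$value[na$route == "dietary"]), 8 * (1.37 - 0.87))

  # exposed identical to control: all zeros
  same <- rbind(make_table("C", 10, 2, 1.52, 0.87),
                make_table("E", 10, 2, 1.52, 0.87))
  na0 <- compute_new_accumulation(same, cfg)
  expect_equal(na0$value, rep(0, nrow(na0)))
})

test_that("accounting linearity and scaling-order invariance", {
  cfg <- tiny_config()
  withr::with_seed(11, {
    for (i in 1:20) {
      tab <- rbind(
        make_table("C", c(10, 20, 30), 3, runif(9, 1, 2), runif(9, 0.5, 1)),
        make_table("E", c(10, 20, 30), 3, runif(9, 2, 9), runif(9, 1, 3)))
      na <- compute_new_accumulation(tab, cfg)
      # linearity: scaling all concentrations by c scales accumulations by c
      cc <- runif(1, 0.1, 10)
      tab2 <- tab
      tab2$conc_w <- cc * tab$conc_w
      tab2$conc_d <- cc * tab$conc_d
      na2 <- compute_new_accumulation(tab2, cfg)
      expect_equal(na2$value, cc * na$value, tolerance = 1e-12)
      # order invariance: S*(exposed - control) == S*exposed - S*control
      S <- attr(na, "scaling_factor")
      bg <- estimate_background(tab, cfg, "dietary")$mean
      pre_scaled <- S * tab$conc_d[tab$group == "E"] - S * bg
      expect_equal(na$value[na$route == "dietary"], pre_scaled,
                   tolerance = 1e-12)
    }
  })
})

test_that("time-matched control subtraction uses per-day means", {
  cfg <- tiny_config()
  tab <- rbind(make_table("C", c(10, 20, 30), 2, c(1.4, 1.4, 1.5, 1.5, 1.6, 1.6),
                          0.87),
               make_table("E", c(10, 20, 30), 2, 5, 1.37))
  na <- compute_new_accumulation(tab, cfg, time_matched = TRUE)
  w <- na[na$route == "waterborne", ]
  expect_equal(unique(w$value[w$day == 10]), 5 - 1.4)
  expect_equal(unique(w$value[w$day == 30]), 5 - 1.6)
})

test_that("negative cell means are flagged, never clipped", {
  cfg <- tiny_config(tiny_design(sample_days = 10))
  tab <- rbind(make_table("C", 10, 3, 1.52, 0.87),
               make_table("E", 10, 3, 1.40, 0.95))  # below background
  na <- compute_new_accumulation(tab, cfg)
  cells <- summarize_new_accumulation(na)
  w <- cells[cells$route == "waterborne", ]
  expect_true(w$flagged_negative)
  expect_lt(w$mean, 0)                     # value preserved, not clipped
  expect_false(cells$flagged_negative[cells$route == "dietary"])
})

test_that("zero-noise pipeline recovers influx * t exactly", {
  sc <- anodonta_scenario(noise_cv = 0)
  tab <- simulate_experiment(sc$config, sc$truth, seed = 3)
  na <- compute_new_accumulation(tab, sc$config)
  for (g in c("T1", "T2", "T3")) {
    for (d in c(10, 20, 30)) {
      w <- na$value[na$group == g & na$day == d & na$route == "waterborne"]
      expect_equal(w, rep(sc$truth$influx_w[[g]] * d, length(w)),
                   tolerance = 1e-12)
      dd <- na$value[na$group == g & na$day == d & na$route == "dietary"]
      expect_equal(dd, rep(sc$truth$influx_d[[g]] * d, length(dd)),
                   tolerance = 1e-12)
    }
  }
})

test_that("QC arithmetic: specificity, spike recovery, total background", {
  sp <- tracer_specificity(2.5, 0.02)
  expect_equal(sp$fraction, 2.5 / 2.52)
  expect_true(sp$pass)
  expect_equal(tracer_specificity(1, 1)$fraction, 0.5)
  expect_false(tracer_specificity(1, 1)$pass)
  expect_true(tracer_specificity(1, 0)$pass)
  expect_error(tracer_specificity(0, 0), class = "undefined_fraction_error")

  expect_equal(qc_spike_recovery(95, 100)$deviation, 0.05)
  expect_true(qc_spike_recovery(95, 100)$pass)
  expect_false(qc_spike_recovery(111, 100)$pass)
  expect_equal(qc_spike_recovery(100, 100)$deviation, 0)
  expect_error(qc_spike_recovery(95, 0), class = "domain_error")

  expect_equal(background_total_cd(1.52, 0.2413), 1.52 / 0.2413)
  expect_equal(background_total_cd(0.87, 0.1222), 0.87 / 0.1222)
  expect_equal(background_total_cd(0, 0.2413), 0)
  expect_error(background_total_cd(1, 1.5), class = "domain_error")
})
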