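# Shared fixtures: a minimal two-group design and a builder for hand-made
# measurement tables.

tiny_design <- function(sample_days = c(10, 20, 30)) {
  exposure_design(
    groups = data.frame(name = c("C", "E"),
                        waterborne_conc = c(0, 5),
                        dietary_conc = c(0.5, 2)),
    tanks_per_group = 1, mussels_per_tank = 10,
    sampled_per_group_time = 3, sample_days = sample_days,
    feeding_hours_per_day = 3, day_hours = 24)
}

tiny_config <- function(design = tiny_design(), ...) {
  analysis_config(
    tracer_spec("Cd112", "waterborne", natural_abundance = 0.2413,
                spike_purity = 0.9870),
    tracer_spec("Cd113", "dietary", natural_abundance = 0.1222,
                spike_purity = 0.9335),
    design, ...)
}

# one row per (group, day, replicate); conc_w / conc_d supplied as vectors
# recycled over rows
make_table <- function(groups, days, n_per_cell, conc_w, conc_d) {
  grid <- expand.grid(rep = seq_len(n_per_cell), day = days, group = groups,
                      stringsAsFactors = FALSE)
  data.frame(group = grid$group, day = grid$day, tank = "t1",
             mussel_id = sprintf("%s-d%g-%d", grid$group, grid$day, grid$rep),
             conc_w = rep_len(conc_w, nrow(grid)),
             conc_d = rep_len(conc_d, nrow(grid)),
             shell_length_cm = 7, dry_weight_g = 1,
             stringsAsFactors = FALSE)
}

# closed-form OLS slope oracle: cov(t, y) / var(t), free intercept
slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}
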