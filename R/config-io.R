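# YAML configuration I/O.  The file mirrors analysis_config field names:
#
# tracers:
#   waterborne: {label: Cd112, route: waterborne, natural_abundance: 0.2413,
#                spike_purity: 0.9870}
#   dietary:    {label: Cd113, route: dietary,    natural_abundance: 0.1222,
#                spike_purity: 0.9335}
# design:
#   groups:
#     - {name: T0, waterborne_conc: 0.0, dietary_conc: 0.8}
#   tanks_per_group: 3
#   ...
# regression_through_origin: false
# bootstrap_reps: 0
# rng_seed: 1
# qc_tolerance: 0.10

#' Read an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [analysis_config()]
#'   fields; see `system.file("extdata", "config.yaml", package =
#'   "dualtracer")` for a complete example.
#' @return An [analysis_config()] object (fully validated).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path))
    dt_stop("io_error", "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  for (k in c("tracers", "design"))
    if (is.null(y[[k]]))
      dt_stop("schema_error", "config is missing required key '%s'", k)
  mk_tracer <- function(t, role) {
    if (is.null(t))
      dt_stop("schema_error", "config tracers block is missing the '%s' tracer", role)
    tracer_spec(t$label, t$route %||% role,
                natural_abundance = t$natural_abundance,
                spike_purity = t$spike_purity %||% 1)
  }
  d <- y$design
  groups <- do.call(rbind, lapply(d$groups, function(g)
    data.frame(name = g$name, waterborne_conc = g$waterborne_conc,
               dietary_conc = g$dietary_conc)))
  design <- exposure_design(groups,
                            tanks_per_group = d$tanks_per_group,
                            mussels_per_tank = d$mussels_per_tank,
                            sampled_per_group_time = d$sampled_per_group_time,
                            sample_days = unlist(d$sample_days),
                            feeding_hours_per_day = d$feeding_hours_per_day,
                            day_hours = d$day_hours %||% 24)
  analysis_config(mk_tracer(y$tracers$waterborne, "waterborne"),
                  mk_tracer(y$tracers$dietary, "dietary"),
                  design,
                  regression_through_origin = y$regression_through_origin %||% FALSE,
                  bootstrap_reps = y$bootstrap_reps %||% 0L,
                  rng_seed = y$rng_seed %||% 1L,
                  qc_tolerance = y$qc_tolerance %||% 0.10)
}

#' Write an analysis configuration to YAML
#'
#' Inverse of [read_analysis_config()]: `read_analysis_config(write_analysis_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config An [analysis_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  d <- config$design
  y <- list(
    tracers = lapply(config$tracers, function(t)
      list(label = t$label, route = t$route,
           natural_abundance = t$natural_abundance,
           spike_purity = t$spike_purity)),
    design = list(
      groups = lapply(seq_len(nrow(d$groups)), function(i)
        list(name = d$groups$name[i],
             waterborne_conc = d$groups$waterborne_conc[i],
             dietary_conc = d$groups$dietary_conc[i])),
      tanks_per_group = d$tanks_per_group,
      mussels_per_tank = d$mussels_per_tank,
      sampled_per_group_time = d$sampled_per_group_time,
      sample_days = d$sample_days,
      feeding_hours_per_day = d$feeding_hours_per_day,
      day_hours = d$day_hours),
    regression_through_origin = config$regression_through_origin,
    bootstrap_reps = config$bootstrap_reps,
    rng_seed = config$rng_seed,
    qc_tolerance = config$qc_tolerance)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read simulation truth parameters from YAML
#'
#' @param path YAML file with keys mirroring [simulation_truth()] fields
#'   (`background_w`, `background_d`, `influx_w`/`influx_d` maps from group
#'   name to rate, `noise_cv`, optional `growth`, `tank_cv`, `noise_law`).
#' @return A [simulation_truth()] object.
#' @export
read_simulation_truth <- function(path) {
  if (!file.exists(path))
    dt_stop("io_error", "truth file not found: %s", path)
  y <- yaml::read_yaml(path)
  g <- y$growth
  simulation_truth(background_w = y$background_w, background_d = y$background_d,
                   influx_w = unlist(y$influx_w), influx_d = unlist(y$influx_d),
                   noise_cv = y$noise_cv %||% 0.10,
                   growth = if (is.null(g)) NULL else
                     list(shell_mean = g$shell_mean, shell_sd = g$shell_sd,
                          weight_mean = g$weight_mean, weight_sd = g$weight_sd),
                   tank_cv = y$tank_cv %||% 0,
                   noise_law = y$noise_law %||% "lognormal")
}

#' Write simulation truth parameters to YAML
#'
#' @param truth A [simulation_truth()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  y <- list(background_w = truth$background_w, background_d = truth$background_d,
            influx_w = as.list(truth$influx_w), influx_d = as.list(truth$influx_d),
            noise_cv = truth$noise_cv, growth = truth$growth,
            tank_cv = truth$tank_cv, noise_law = truth$noise_law)
  yaml::write_yaml(y, path)
  invisible(path)
}
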