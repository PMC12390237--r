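#' Define an isotope tracer
#'
#' A tracer is one stable isotope of the study metal assigned to a single
#' exposure route.  A dual-tracer analysis uses exactly two: one waterborne
#' and one dietary.
#'
#' @param label Isotope name, e.g. `"Cd112"`.
#' @param route Exposure route the tracer labels: `"waterborne"` or
#'   `"dietary"`.
#' @param natural_abundance Fraction of the element naturally occurring as
#'   this isotope, in (0, 1).  Used to infer total background metal from the
#'   tracer concentration in unexposed tissue (see [background_total_cd()]).
#' @param spike_purity Isotopic enrichment of the purchased spike, in (0, 1].
#'   Recorded for provenance; concentrations are not purity-corrected by
#'   default.
#' @return An object of class `tracer_spec`.
#' @examples
#' tracer_spec("Cd112", "waterborne", natural_abundance = 0.2413,
#'             spike_purity = 0.9870)
#' @export
tracer_spec <- function(label, route = c("waterborne", "dietary"),
                        natural_abundance, spike_purity = 1) {
  route <- match.arg(route)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(natural_abundance) || length(natural_abundance) != 1L ||
      natural_abundance <= 0 || natural_abundance >= 1)
    dt_stop("domain_error", "natural_abundance must lie strictly in (0, 1), got %s",
            format(natural_abundance))
  if (!is.numeric(spike_purity) || length(spike_purity) != 1L ||
      spike_purity <= 0 || spike_purity > 1)
    dt_stop("domain_error", "spike_purity must lie in (0, 1], got %s",
            format(spike_purity))
  structure(list(label = label, route = route,
                 natural_abundance = natural_abundance,
                 spike_purity = spike_purity),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer_spec> %s (%s route), natural abundance %.4f, spike purity %.4f\n",
              x$label, x$route, x$natural_abundance, x$spike_purity))
  invisible(x)
}

#' Describe an exposure design
#'
#' The design records the treatment groups with their nominal exposure
#' levels, the replication structure (tanks, animals), the sampling schedule
#' and the daily feeding window.  Exactly one group must have
#' `waterborne_conc == 0`; it is the control used for background estimation.
#'
#' @param groups A data frame with columns `name`, `waterborne_conc`
#'   (water tracer, ug/L) and `dietary_conc` (food tracer, ug/g dw).
#' @param tanks_per_group Number of replicate tanks per group.
#' @param mussels_per_tank Animals stocked per tank.
#' @param sampled_per_group_time Animals sampled per group at each sampling
#'   day (spread evenly across tanks).
#' @param sample_days Strictly increasing positive sampling days.
#' @param feeding_hours_per_day Duration of the daily feeding window, hours.
#' @param day_hours Hours in a day (default 24); the dietary daily-equivalent
#'   scaling factor is `day_hours / feeding_hours_per_day`.
#' @return An object of class `exposure_design`.
#' @seealso [dietary_scaling_factor()], [anodonta_scenario()]
#' @export
exposure_design <- function(groups, tanks_per_group, mussels_per_tank,
                            sampled_per_group_time, sample_days,
                            feeding_hours_per_day, day_hours = 24) {
  groups <- as.data.frame(groups)
  need <- c("name", "waterborne_conc", "dietary_conc")
  if (!all(need %in% names(groups)))
    dt_stop("schema_error", "groups must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(groups$name))
    dt_stop("validation_error", "duplicate group names")
  if (any(groups$waterborne_conc < 0) || any(groups$dietary_conc < 0))
    dt_stop("validation_error", "exposure concentrations must be >= 0")
  n_ctrl <- sum(groups$waterborne_conc == 0)
  if (n_ctrl != 1L)
    dt_stop("validation_error",
            "exactly one group must have waterborne_conc == 0 (the control); found %d", n_ctrl)
  if (length(sample_days) < 1L || any(sample_days <= 0) ||
      is.unsorted(sample_days, strictly = TRUE))
    dt_stop("validation_error", "sample_days must be strictly increasing and positive")
  if (feeding_hours_per_day <= 0 || feeding_hours_per_day > day_hours)
    dt_stop("domain_error", "feeding_hours_per_day must lie in (0, day_hours]")
  stopifnot(tanks_per_group >= 1, mussels_per_tank >= 1,
            sampled_per_group_time >= 1)
  structure(list(groups = groups,
                 tanks_per_group = as.integer(tanks_per_group),
                 mussels_per_tank = as.integer(mussels_per_tank),
                 sampled_per_group_time = as.integer(sampled_per_group_time),
                 sample_days = as.numeric(sample_days),
                 feeding_hours_per_day = as.numeric(feeding_hours_per_day),
                 day_hours = as.numeric(day_hours)),
            class = "exposure_design")
}

#' @export
print.exposure_design <- function(x, ...) {
  cat(sprintf("<exposure_design> %d groups (%s), %d tanks/group x %d animals, sampled %d/group on days %s\n",
              nrow(x$groups), paste(x$groups$name, collapse = ", "),
              x$tanks_per_group, x$mussels_per_tank, x$sampled_per_group_time,
              paste(x$sample_days, collapse = "/")))
  cat(sprintf("  feeding %g h of %g h per day (dietary scaling factor %g)\n",
              x$feeding_hours_per_day, x$day_hours,
              x$day_hours / x$feeding_hours_per_day))
  invisible(x)
}

#' Name of the control group in a design
#'
#' @param design An [exposure_design()].
#' @return The name of the (unique) group with zero waterborne exposure.
#' @export
control_group <- function(design) {
  stopifnot(inherits(design, "exposure_design"))
  design$groups$name[design$groups$waterborne_conc == 0][1L]
}

#' Assemble a full analysis configuration
#'
#' Bundles the two tracer definitions, the exposure design and the analysis
#' switches that downstream stages consult.
#'
#' @param waterborne,dietary [tracer_spec()] objects for the two routes.
#' @param design An [exposure_design()].
#' @param regression_through_origin If `TRUE`, influx regressions are forced
#'   through the origin.  Default `FALSE`: background subtraction should
#'   already leave a near-zero intercept and forcing it is an untestable
#'   assumption.
#' @param bootstrap_reps Default bootstrap replicate count for
#'   [bootstrap_apportionment()] (0 disables).
#' @param rng_seed Default seed for stochastic steps.
#' @param qc_tolerance Maximum allowed relative deviation in spike-recovery
#'   QC, default 0.10.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(waterborne, dietary, design,
                            regression_through_origin = FALSE,
                            bootstrap_reps = 0L, rng_seed = 1L,
                            qc_tolerance = 0.10) {
  stopifnot(inherits(waterborne, "tracer_spec"), inherits(dietary, "tracer_spec"),
            inherits(design, "exposure_design"))
  if (waterborne$route != "waterborne" || dietary$route != "dietary")
    dt_stop("validation_error",
            "need exactly one waterborne and one dietary tracer (got %s + %s)",
            waterborne$route, dietary$route)
  if (bootstrap_reps < 0)
    dt_stop("validation_error", "bootstrap_reps must be >= 0")
  if (qc_tolerance <= 0 || qc_tolerance >= 1)
    dt_stop("domain_error", "qc_tolerance must lie strictly in (0, 1)")
  structure(list(tracers = list(waterborne = waterborne, dietary = dietary),
                 design = design,
                 regression_through_origin = isTRUE(regression_through_origin),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rng_seed = as.integer(rng_seed),
                 qc_tolerance = qc_tolerance),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> tracers %s (waterborne) + %s (dietary)\n",
              x$tracers$waterborne$label, x$tracers$dietary$label))
  print(x$design)
  cat(sprintf("  regression through origin: %s; bootstrap reps: %d; qc tolerance: %g\n",
              x$regression_through_origin, x$bootstrap_reps, x$qc_tolerance))
  invisible(x)
}

# internal: concentration column name for a tracer in the CSV schema
tracer_column <- function(tracer) paste0(tolower(tracer$label), "_ugg_dw")
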