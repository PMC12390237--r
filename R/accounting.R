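# Tracer accounting: background estimation, feeding-window scaling, new
# accumulation, and the QC arithmetic (tracer specificity, spike recovery,
# total-metal back-calculation from natural abundance).

#' Daily-equivalent scaling factor for a limited feeding window
#'
#' Animals that filter-feed around the clock ingest food only while food is
#' present.  Dietary-tracer measurements made under a restricted feeding
#' window are referred to a full day by multiplying by
#' `day_hours / feeding_hours` (e.g. a 3-hour window in a 24-hour day gives
#' a factor of 8).
#'
#' @param feeding_hours Feeding window duration, hours.
#' @param day_hours Hours per day (default 24).
#' @return The dimensionless scaling factor.
#' @examples
#' dietary_scaling_factor(3, 24)  # 8
#' @export
dietary_scaling_factor <- function(feeding_hours, day_hours = 24) {
  if (!is.numeric(feeding_hours) || feeding_hours <= 0 ||
      !is.numeric(day_hours) || day_hours <= 0 || feeding_hours > day_hours)
    dt_stop("domain_error",
            "need 0 < feeding_hours <= day_hours (got %s, %s)",
            format(feeding_hours), format(day_hours))
  day_hours / feeding_hours
}

#' Estimate the background tracer concentration from the control group
#'
#' The background is the tracer level carried by unexposed animals (natural
#' isotopic composition of the ambient metal burden).  By default it is the
#' control-group mean pooled over all sampling days; per-day means are
#' retained for inspection and for time-matched subtraction.
#'
#' @param table A validated measurement table.
#' @param config An [analysis_config()].
#' @param route `"waterborne"` or `"dietary"`: which tracer's background.
#' @return An object of class `background_estimate` with fields `tracer`,
#'   `route`, `mean`, `sd`, `n` and `per_day` (named vector of per-day
#'   means).
#' @export
estimate_background <- function(table, config,
                                route = c("waterborne", "dietary")) {
  route <- match.arg(route)
  stopifnot(inherits(config, "analysis_config"))
  ctrl <- control_group(config$design)
  rows <- table[table$group == ctrl, , drop = FALSE]
  if (nrow(rows) == 0L)
    dt_stop("missing_control_error",
            "no control-group ('%s') rows in the measurement table", ctrl)
  x <- if (route == "waterborne") rows$conc_w else rows$conc_d
  per_day <- tapply(x, rows$day, mean)
  structure(list(tracer = config$tracers[[route]]$label, route = route,
                 mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 n = length(x),
                 per_day = setNames(as.numeric(per_day), names(per_day))),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> %s (%s): %.4g +/- %.4g ug/g dw (n = %d)\n",
              x$tracer, x$route, x$mean, x$sd, x$n))
  invisible(x)
}

#' Compute per-animal new accumulation of both tracers
#'
#' New accumulation is the tissue tracer concentration minus the control
#' (background) concentration.  Dietary values are additionally multiplied by
#' the daily-equivalent scaling factor S = `day_hours / feeding_hours`, so
#' both routes end up on a common per-day basis.  By linearity, scaling
#' before or after subtraction is identical; this implementation subtracts
#' first.
#'
#' @param table A validated measurement table.
#' @param config An [analysis_config()].
#' @param time_matched If `TRUE`, subtract the control mean of the same
#'   sampling day instead of the pooled control mean.  Default `FALSE`
#'   (pooled): lower variance, and appropriate when the control shows no
#'   trend.
#' @return A data frame of class `new_accumulation` with one row per
#'   non-control animal and tracer: columns `group`, `day`, `tank`,
#'   `mussel_id`, `route`, `tracer`, `value` (ug/g dw, dietary values
#'   daily-equivalent).  The background estimates used are attached as
#'   attributes `background_w` / `background_d`; `scaling_factor` holds S.
#' @seealso [summarize_new_accumulation()] for the per-cell summary.
#' @export
compute_new_accumulation <- function(table, config, time_matched = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  bg_w <- estimate_background(table, config, "waterborne")
  bg_d <- estimate_background(table, config, "dietary")
  S <- dietary_scaling_factor(config$design$feeding_hours_per_day,
                              config$design$day_hours)
  ctrl <- control_group(config$design)
  exp_rows <- table[table$group != ctrl, , drop = FALSE]
  if (nrow(exp_rows) == 0L)
    dt_stop("validation_error", "no non-control rows in the measurement table")
  bg_at <- function(bg, day) {
    if (time_matched && as.character(day) %in% names(bg$per_day))
      bg$per_day[[as.character(day)]] else bg$mean
  }
  base <- exp_rows[c("group", "day", "tank", "mussel_id")]
  w <- cbind(base, route = "waterborne",
             tracer = config$tracers$waterborne$label,
             value = exp_rows$conc_w -
               vapply(exp_rows$day, function(d) bg_at(bg_w, d), numeric(1)))
  d <- cbind(base, route = "dietary",
             tracer = config$tracers$dietary$label,
             value = S * (exp_rows$conc_d -
               vapply(exp_rows$day, function(dd) bg_at(bg_d, dd), numeric(1))))
  out <- rbind(w, d)
  rownames(out) <- NULL
  structure(out, class = c("new_accumulation", "data.frame"),
            background_w = bg_w, background_d = bg_d, scaling_factor = S,
            time_matched = time_matched)
}

#' Summarize new accumulation per group x day x tracer cell
#'
#' @param newaccum Output of [compute_new_accumulation()].
#' @return A data frame with one row per (group, day, route): columns
#'   `group`, `day`, `route`, `tracer`, `mean`, `sd`, `n`,
#'   `flagged_negative` (`TRUE` when the cell mean is negative, i.e. noise
#'   exceeded signal; such cells are reported, never clipped).
#' @export
summarize_new_accumulation <- function(newaccum) {
  stopifnot(inherits(newaccum, "new_accumulation"))
  sp <- split(newaccum,
              list(newaccum$group, newaccum$day, newaccum$route), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(cell) {
    data.frame(group = cell$group[1L], day = cell$day[1L],
               route = cell$route[1L], tracer = cell$tracer[1L],
               mean = mean(cell$value),
               sd = if (nrow(cell) > 1L) stats::sd(cell$value) else 0,
               n = nrow(cell),
               flagged_negative = mean(cell$value) < 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$day, out$route), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tracer specificity check
#'
#' In a dual-tracer spike the labelled isotope should dominate the total
#' label in its own matrix (water or food): the check passes when
#' `target / (target + other)` reaches the threshold (default 0.99, i.e. the
#' other isotope contributes under 1% and is negligible).
#'
#' @param conc_target Concentration of the tracer that should dominate.
#' @param conc_other Concentration of the other tracer in the same matrix.
#' @param threshold Minimum acceptable fraction (default 0.99).
#' @return A list with `fraction` and logical `pass`.
#' @examples
#' tracer_specificity(2.5, 0.02)  # fraction ~0.992, pass
#' @export
tracer_specificity <- function(conc_target, conc_other, threshold = 0.99) {
  if (conc_target < 0 || conc_other < 0)
    dt_stop("domain_error", "concentrations must be >= 0")
  if (conc_target + conc_other == 0)
    dt_stop("undefined_fraction_error",
            "both concentrations are zero; specificity fraction undefined")
  frac <- conc_target / (conc_target + conc_other)
  list(fraction = frac, pass = frac >= threshold)
}

#' Spike-recovery QC check
#'
#' Compares a measured concentration of a reference material against its
#' certified value; the run passes when the relative deviation is below the
#' tolerance (default 10%).
#'
#' @param measured Measured concentration.
#' @param certified Certified concentration (> 0).
#' @param tolerance Maximum allowed relative deviation (default 0.10).
#' @return A list with `deviation` (|measured - certified| / certified) and
#'   logical `pass`.
#' @export
qc_spike_recovery <- function(measured, certified, tolerance = 0.10) {
  if (!is.numeric(certified) || certified <= 0)
    dt_stop("domain_error", "certified value must be > 0")
  dev <- abs(measured - certified) / certified
  list(deviation = dev, pass = dev < tolerance)
}

#' Infer total background metal from one tracer isotope
#'
#' In unexposed tissue the metal has natural isotopic composition, so the
#' total metal burden is the tracer-isotope concentration divided by that
#' isotope's natural abundance.  Used to compare background burdens against
#' regulatory total-metal limits.
#'
#' @param tracer_conc Background tracer concentration (ug/g dw).
#' @param natural_abundance Natural abundance fraction of the isotope,
#'   in (0, 1).
#' @return Estimated total metal concentration (ug/g dw).
#' @examples
#' background_total_cd(1.52, 0.2413)  # ~6.3 ug/g dw total Cd
#' @export
background_total_cd <- function(tracer_conc, natural_abundance) {
  if (!is.numeric(natural_abundance) || natural_abundance <= 0 ||
      natural_abundance >= 1)
    dt_stop("domain_error", "natural_abundance must lie strictly in (0, 1)")
  if (any(tracer_conc < 0))
    dt_stop("domain_error", "tracer_conc must be >= 0")
  tracer_conc / natural_abundance
}
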