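# Influx-rate estimation: ordinary least squares of new accumulation against
# exposure time, per group and tracer.

#' Estimate an influx rate for one group and tracer
#'
#' The influx rate J_in (ug/g/d) is the slope of new accumulation on
#' exposure day, fitted by ordinary least squares over the per-animal
#' replicate values.  With a free intercept (the default) at least two
#' distinct days are required; through the origin one suffices.  No
#' synthetic (day 0, accumulation 0) point is added.
#'
#' @param newaccum Output of [compute_new_accumulation()], or any data frame
#'   with columns `day` and `value` (plus `group`/`route` if `group`/`route`
#'   filters are used).
#' @param group,route Optional filters selecting one group x tracer slice;
#'   omit them if `newaccum` is already a single slice.
#' @param through_origin Force the regression through the origin
#'   (default `FALSE`).
#' @return An object of class `influx_estimate`: fields `group`, `tracer`,
#'   `route`, `j_in`, `slope_se`, `intercept` (0 when through origin),
#'   `r_squared`, `n_points`, `through_origin`.
#' @examples
#' pts <- data.frame(day = c(10, 20, 30), value = c(6.2, 12.4, 18.6))
#' estimate_influx(pts)$j_in  # 0.62
#' @export
estimate_influx <- function(newaccum, group = NULL, route = NULL,
                            through_origin = FALSE) {
  df <- as.data.frame(newaccum)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (!is.null(route)) df <- df[df$route == route, , drop = FALSE]
  if (!all(c("day", "value") %in% names(df)))
    dt_stop("schema_error", "need columns 'day' and 'value'")
  n_days <- length(unique(df$day))
  if (nrow(df) == 0L || (through_origin && n_days < 1L) ||
      (!through_origin && n_days < 2L))
    dt_stop("insufficient_data_error",
            "need >= %d distinct day(s), got %d",
            if (through_origin) 1L else 2L, n_days)
  if (!through_origin && stats::var(df$day) == 0)
    dt_stop("degenerate_design_error", "zero variance in day")
  fit <- if (through_origin) stats::lm(value ~ day + 0, data = df)
         else stats::lm(value ~ day, data = df)
  # exact (noise-free) data triggers summary.lm's "essentially perfect fit"
  # warning; the slope and SE are still what we need
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  structure(list(group = if (!is.null(df$group)) df$group[1L] else NA_character_,
                 tracer = if (!is.null(df$tracer)) df$tracer[1L] else NA_character_,
                 route = if (!is.null(df$route)) df$route[1L] else NA_character_,
                 j_in = unname(co["day", "Estimate"]),
                 slope_se = unname(co["day", "Std. Error"]),
                 intercept = if (through_origin) 0
                             else unname(co["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared,
                 n_points = nrow(df),
                 through_origin = through_origin),
            class = "influx_estimate")
}

#' @export
print.influx_estimate <- function(x, ...) {
  cat(sprintf("<influx_estimate> %s %s: J_in = %.4g +/- %.4g ug/g/d (R2 = %.3f, n = %d%s)\n",
              x$group, x$tracer %||% "", x$j_in, x$slope_se, x$r_squared,
              x$n_points, if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Estimate influx rates for all treatment groups and both tracers
#'
#' @param newaccum Output of [compute_new_accumulation()].
#' @param through_origin Passed to [estimate_influx()].
#' @return A data frame with one row per (group, route): columns `group`,
#'   `route`, `tracer`, `j_in`, `slope_se`, `intercept`, `r_squared`,
#'   `n_points`.  The underlying `influx_estimate` objects are attached as
#'   attribute `estimates`.
#' @export
estimate_influx_all <- function(newaccum, through_origin = FALSE) {
  stopifnot(inherits(newaccum, "new_accumulation"))
  sp <- split(newaccum, list(newaccum$group, newaccum$route), drop = TRUE)
  ests <- lapply(sp, estimate_influx, through_origin = through_origin)
  out <- do.call(rbind, lapply(ests, function(e)
    data.frame(group = e$group, route = e$route, tracer = e$tracer,
               j_in = e$j_in, slope_se = e$slope_se, intercept = e$intercept,
               r_squared = e$r_squared, n_points = e$n_points,
               stringsAsFactors = FALSE)))
  out <- out[order(out$route, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "estimates") <- ests
  out
}

#' Summarize influx rates across treatment groups for one tracer
#'
#' @param estimates Either the data frame from [estimate_influx_all()] or a
#'   list of `influx_estimate` objects.
#' @param route `"waterborne"` or `"dietary"`.
#' @return An object of class `influx_summary`: `tracer`, `route`,
#'   `mean_j_in`, `sd_j_in` (sample SD, n-1; 0 with a warning for a single
#'   group), `min_j_in`, `max_j_in`, `n_groups`, `per_group` (named slope
#'   vector).
#' @export
summarize_influx <- function(estimates, route = c("waterborne", "dietary")) {
  route <- match.arg(route)
  df <- if (is.data.frame(estimates)) estimates else
    do.call(rbind, lapply(estimates, function(e)
      data.frame(group = e$group, route = e$route, tracer = e$tracer,
                 j_in = e$j_in, stringsAsFactors = FALSE)))
  df <- df[df$route == route, , drop = FALSE]
  if (nrow(df) == 0L)
    dt_stop("insufficient_data_error", "no influx estimates for route '%s'", route)
  slopes <- setNames(df$j_in, df$group)
  sd_j <- if (length(slopes) > 1L) stats::sd(slopes) else {
    warning("single influx estimate: SD undefined, reported as 0")
    0
  }
  structure(list(tracer = df$tracer[1L], route = route,
                 mean_j_in = mean(slopes), sd_j_in = sd_j,
                 min_j_in = min(slopes), max_j_in = max(slopes),
                 n_groups = length(slopes), per_group = slopes),
            class = "influx_summary")
}

#' @export
print.influx_summary <- function(x, ...) {
  cat(sprintf("<influx_summary> %s (%s): J_in = %.3g +/- %.3g ug/g/d (range %.3g-%.3g, %d groups)\n",
              x$tracer, x$route, x$mean_j_in, x$sd_j_in, x$min_j_in,
              x$max_j_in, x$n_groups))
  invisible(x)
}

#' Fold difference between mean waterborne and dietary influx rates
#'
#' @param summary_w,summary_d [summarize_influx()] results (or any objects
#'   with a `mean_j_in` field) for the numerator and denominator routes.
#' @return The dimensionless fold `mean_j_in(w) / mean_j_in(d)`.
#' @examples
#' influx_ratio(list(mean_j_in = 0.62), list(mean_j_in = 0.05))  # 12.4
#' @export
influx_ratio <- function(summary_w, summary_d) {
  jw <- summary_w$mean_j_in
  jd <- summary_d$mean_j_in
  if (!is.numeric(jd) || jd <= 0)
    dt_stop("domain_error", "denominator mean influx must be > 0")
  jw / jd
}
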