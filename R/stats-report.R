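# Supporting statistics: growth comparisons across groups (one-way ANOVA
# with Tukey HSD compact letter display), the paired comparison of the two
# routes' relative importance, and the assembled JSON analysis report.

# compact letter display from a named vector of pairwise p-values
# ("A-B" -> p).  Greedy insertion: groups not significantly different share
# a letter.  Small group counts only (4 groups here), so the simple
# algorithm suffices.
compact_letters <- function(groups, pvals, alpha = 0.05) {
  differ <- list()
  for (nm in names(pvals)) {
    if (!is.na(pvals[[nm]]) && pvals[[nm]] < alpha) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1L]]
      differ[[length(differ) + 1L]] <- pair
    }
  }
  sets <- list()  # each set: character vector of mutually compatible groups
  compatible <- function(set, g)
    !any(vapply(differ, function(p)
      (p[1L] == g && p[2L] %in% set) || (p[2L] == g && p[1L] %in% set),
      logical(1)))
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (compatible(sets[[i]], g)) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[[g]] <- paste0(letters_out[[g]], letters[i])
  letters_out
}

#' Compare growth variables across groups
#'
#' One-way ANOVA of shell length and soft-tissue dry weight across groups,
#' separately for each sampling day, with Tukey HSD pairwise comparisons
#' summarized as a compact letter display (groups sharing a letter do not
#' differ at `alpha`).  Classical (equal-variance) one-way ANOVA; no
#' multiple-testing correction across days or variables.
#'
#' @param table A validated measurement table.
#' @param alpha Significance level (default 0.05).
#' @return A data frame of class `growth_comparison`, one row per
#'   (variable, day): columns `variable`, `day`, `test`, `statistic` (F),
#'   `df1`, `df2`, `p_value`, `significant`, `letters` (compact letter
#'   display, "group=letter" pairs).
#' @export
compare_growth <- function(table, alpha = 0.05) {
  vars <- c(shell_length = "shell_length_cm", dry_weight = "dry_weight_g")
  groups <- unique(table$group)
  if (length(groups) < 2L)
    dt_stop("insufficient_data_error", "need >= 2 groups, got %d", length(groups))
  rows <- list()
  for (v in names(vars)) {
    for (d in sort(unique(table$day))) {
      sub <- table[table$day == d, , drop = FALSE]
      cnt <- table(sub$group)
      if (length(cnt) < 2L || any(cnt < 2L))
        dt_stop("insufficient_data_error",
                "day %g: need >= 2 animals in each of >= 2 groups", d)
      sub$g <- factor(sub$group)
      fml <- stats::as.formula(paste(vars[[v]], "~ g"))
      fit <- stats::aov(fml, data = sub)
      an <- stats::anova(fit)
      tk <- stats::TukeyHSD(fit)$g
      cld <- compact_letters(levels(sub$g), setNames(tk[, "p adj"],
                                                     rownames(tk)), alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, day = d, test = "one_way_anova",
        statistic = an[1L, "F value"], df1 = an[1L, "Df"], df2 = an[2L, "Df"],
        p_value = an[1L, "Pr(>F)"],
        significant = an[1L, "Pr(>F)"] < alpha,
        letters = paste(sprintf("%s=%s", names(cld), cld), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("growth_comparison", "data.frame"))
}

#' Paired comparison of the two routes' relative importance
#'
#' Paired t-test of the waterborne versus dietary share across apportionment
#' cells.  Swapping the two routes flips the sign of the statistic and
#' leaves the p-value unchanged.
#'
#' @param cells Output of [apportion_cells()].
#' @param alpha Significance level (default 0.05).
#' @return A list of class `importance_comparison`: `test`, `statistic`,
#'   `df`, `p_value`, `significant`, `mean_difference` (waterborne minus
#'   dietary, percentage points), `n_cells`.
#' @export
compare_importance <- function(cells, alpha = 0.05) {
  ok <- cells[!cells$excluded, , drop = FALSE]
  if (nrow(ok) < 2L)
    dt_stop("insufficient_data_error",
            "need >= 2 non-excluded cells, got %d", nrow(ok))
  diffs <- ok$frac_waterborne - ok$frac_dietary
  if (stats::sd(diffs) == 0) {
    # constant difference: t undefined; significance decided by sign
    res <- list(statistic = if (diffs[1L] == 0) 0 else Inf * sign(diffs[1L]),
                parameter = length(diffs) - 1L,
                p.value = if (diffs[1L] == 0) 1 else 0)
  } else {
    res <- stats::t.test(ok$frac_waterborne, ok$frac_dietary, paired = TRUE)
  }
  structure(list(test = "paired_t_test",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 significant = res$p.value < alpha,
                 mean_difference = mean(diffs),
                 n_cells = nrow(ok)),
            class = "importance_comparison")
}

#' @export
print.importance_comparison <- function(x, ...) {
  cat(sprintf("<importance_comparison> paired t = %.3g (df = %g), p = %.3g%s; mean difference %.1f points over %d cells\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) " (significant)" else "",
              x$mean_difference, x$n_cells))
  invisible(x)
}

#' Run the full dual-tracer analysis pipeline
#'
#' Accounting (backgrounds, new accumulation), kinetics (influx rates and
#' summaries), apportionment (per-cell shares, summary, optional bootstrap),
#' and supporting statistics, assembled into a single report list.
#'
#' @param table A validated measurement table.
#' @param config An [analysis_config()].
#' @param bootstrap_reps Bootstrap replicates for the mean waterborne share
#'   (default from `config`; 0 disables).
#' @param seed Seed for the bootstrap (default from `config`).
#' @return A report list of class `dualtracer_report`; see [build_report()]
#'   for the structure.  Serialize with [write_report_json()].
#' @examples
#' sc <- anodonta_scenario(noise_cv = 0.05)
#' tab <- simulate_experiment(sc$config, sc$truth, seed = 7)
#' rep <- run_analysis(tab, sc$config)
#' rep$apportionment$summary$mean_w
#' @export
run_analysis <- function(table, config, bootstrap_reps = NULL, seed = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  table <- validate_measurements(table, config$design)
  bootstrap_reps <- bootstrap_reps %||% config$bootstrap_reps
  seed <- seed %||% config$rng_seed
  newaccum <- compute_new_accumulation(table, config)
  influx <- estimate_influx_all(newaccum,
                                through_origin = config$regression_through_origin)
  sum_w <- summarize_influx(influx, "waterborne")
  sum_d <- summarize_influx(influx, "dietary")
  cells <- suppressWarnings(apportion_cells(newaccum))
  app_summary <- summarize_apportionment(cells)
  boot <- if (bootstrap_reps >= 100)
    bootstrap_apportionment(table, config, reps = bootstrap_reps, seed = seed)
  build_report(config = config,
               background_w = attr(newaccum, "background_w"),
               background_d = attr(newaccum, "background_d"),
               newaccum = newaccum, influx = influx,
               influx_summary_w = sum_w, influx_summary_d = sum_d,
               cells = cells, apportionment_summary = app_summary,
               growth = compare_growth(table),
               importance = compare_importance(cells),
               bootstrap = boot)
}

#' Assemble stage outputs into a report
#'
#' @param config An [analysis_config()].
#' @param background_w,background_d [estimate_background()] results.
#' @param newaccum [compute_new_accumulation()] result.
#' @param influx [estimate_influx_all()] result.
#' @param influx_summary_w,influx_summary_d [summarize_influx()] results.
#' @param cells [apportion_cells()] result.
#' @param apportionment_summary [summarize_apportionment()] result.
#' @param growth [compare_growth()] result.
#' @param importance [compare_importance()] result.
#' @param bootstrap Optional [bootstrap_apportionment()] result.
#' @return A nested list of class `dualtracer_report` with blocks
#'   `settings`, `backgrounds`, `new_accumulation` (per-cell summary),
#'   `influx` (per-group estimates plus per-route summaries and the
#'   waterborne:dietary fold), `apportionment` (cells, summary, optional
#'   bootstrap CI) and `comparisons`.
#' @export
build_report <- function(config = NULL, background_w = NULL,
                         background_d = NULL, newaccum = NULL, influx = NULL,
                         influx_summary_w = NULL, influx_summary_d = NULL,
                         cells = NULL, apportionment_summary = NULL,
                         growth = NULL, importance = NULL, bootstrap = NULL) {
  for (arg in list(config, background_w, background_d, newaccum, influx,
                   influx_summary_w, influx_summary_d, cells,
                   apportionment_summary, growth, importance))
    if (is.null(arg))
      dt_stop("dependency_error", "a required stage output is missing")
  S <- attr(newaccum, "scaling_factor")
  unsum <- function(s) s[setdiff(names(s), "per_group")]
  list_summary <- function(s) c(unsum(unclass(s)),
                                list(per_group = as.list(s$per_group)))
  structure(list(
    settings = list(
      tracers = lapply(config$tracers, unclass),
      dietary_scaling_factor = S,
      time_matched_control = isTRUE(attr(newaccum, "time_matched")),
      regression_through_origin = config$regression_through_origin,
      qc_tolerance = config$qc_tolerance),
    backgrounds = list(waterborne = unclass(background_w),
                       dietary = unclass(background_d)),
    new_accumulation = summarize_new_accumulation(newaccum),
    influx = list(per_group = as.data.frame(influx),
                  waterborne = list_summary(influx_summary_w),
                  dietary = list_summary(influx_summary_d),
                  fold_w_over_d = influx_ratio(influx_summary_w,
                                               influx_summary_d)),
    apportionment = list(cells = as.data.frame(cells),
                         summary = unclass(apportionment_summary),
                         bootstrap_ci = if (!is.null(bootstrap))
                           list(low = bootstrap$low, high = bootstrap$high,
                                reps = bootstrap$reps)),
    comparisons = list(growth = as.data.frame(growth),
                       importance = unclass(importance))),
    class = "dualtracer_report")
}

#' Serialize a report to JSON
#'
#' @param report A `dualtracer_report` from [run_analysis()] /
#'   [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.  Output is deterministic for a fixed report
#'   (no timestamps).
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "dualtracer_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.dualtracer_report <- function(x, ...) {
  cat("<dualtracer_report>\n")
  cat(sprintf("  backgrounds: %.3g (waterborne) / %.3g (dietary) ug/g dw\n",
              x$backgrounds$waterborne$mean, x$backgrounds$dietary$mean))
  cat(sprintf("  J_in waterborne %.3g +/- %.3g, dietary %.3g +/- %.3g ug/g/d (fold %.3g)\n",
              x$influx$waterborne$mean_j_in, x$influx$waterborne$sd_j_in,
              x$influx$dietary$mean_j_in, x$influx$dietary$sd_j_in,
              x$influx$fold_w_over_d))
  cat(sprintf("  waterborne share %.1f +/- %.1f%% over %d cells (ratio %.3g)\n",
              x$apportionment$summary$mean_w, x$apportionment$summary$sd_w,
              x$apportionment$summary$n_cells, x$apportionment$summary$ratio))
  invisible(x)
}
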