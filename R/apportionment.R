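# Source apportionment: relative importance of the waterborne vs dietary
# route, per group x day cell, with a nonparametric bootstrap for the mean.

#' Apportion one group x day cell between the two routes
#'
#' Relative importance of the waterborne route is
#' `100 * mean_w / (mean_w + mean_d)` where the means are cell means of new
#' accumulation (dietary already daily-equivalent).  Cells in which either
#' mean is negative, or the sum is non-positive, are flagged `excluded`:
#' there the noise exceeded the signal and a ratio would be meaningless.
#'
#' @param mean_w,mean_d Cell means of waterborne and dietary new
#'   accumulation (ug/g dw).
#' @param group,day Cell identity (carried through for reporting).
#' @return A one-row data frame with `group`, `day`, `mean_w`, `mean_d`,
#'   `frac_waterborne`, `frac_dietary` (percent; `NA` when excluded) and
#'   logical `excluded`.
#' @examples
#' apportion_cell(9.16, 0.84)  # 91.6% waterborne
#' @export
apportion_cell <- function(mean_w, mean_d, group = NA_character_, day = NA_real_) {
  excluded <- (mean_w < 0) || (mean_d < 0) || (mean_w + mean_d <= 0)
  if (excluded) {
    fw <- fd <- NA_real_
  } else {
    fw <- 100 * mean_w / (mean_w + mean_d)
    fd <- 100 - fw
  }
  data.frame(group = group, day = day, mean_w = mean_w, mean_d = mean_d,
             frac_waterborne = fw, frac_dietary = fd, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Apportion every group x day cell of a new-accumulation table
#'
#' Pairs the waterborne and dietary cell means for each treatment group and
#' sampling day and computes the relative importance of each route.
#'
#' @param newaccum Output of [compute_new_accumulation()].
#' @return A data frame of class `apportionment_cells`, one row per
#'   (group, day), columns as in [apportion_cell()].  Excluded cells are
#'   reported with a warning, never silently dropped.
#' @export
apportion_cells <- function(newaccum) {
  cells <- summarize_new_accumulation(newaccum)
  w <- cells[cells$route == "waterborne", , drop = FALSE]
  d <- cells[cells$route == "dietary", , drop = FALSE]
  key_w <- paste(w$group, w$day)
  key_d <- paste(d$group, d$day)
  if (!setequal(key_w, key_d))
    dt_stop("pairing_error",
            "waterborne and dietary cells do not pair up by (group, day)")
  d <- d[match(key_w, key_d), , drop = FALSE]
  out <- do.call(rbind, Map(apportion_cell, w$mean, d$mean, w$group, w$day))
  rownames(out) <- NULL
  out <- out[order(out$group, out$day), , drop = FALSE]
  if (any(out$excluded))
    warning(sprintf("%d cell(s) excluded from apportionment (negative mean accumulation): %s",
                    sum(out$excluded),
                    paste(sprintf("%s/day %g", out$group[out$excluded],
                                  out$day[out$excluded]), collapse = ", ")))
  structure(out, class = c("apportionment_cells", "data.frame"))
}

#' Summarize apportionment across cells
#'
#' @param cells Output of [apportion_cells()] (or any data frame with
#'   `frac_waterborne`, `frac_dietary`, `excluded`).
#' @return An object of class `apportionment_summary`: `mean_w`, `sd_w`,
#'   `range_w`, `mean_d`, `sd_d`, `range_d` (percent, over non-excluded
#'   cells; sample SD), `ratio` (= mean_w / mean_d), `n_cells`, `n_excluded`.
#' @examples
#' cells <- rbind(apportion_cell(90, 10), apportion_cell(92, 8),
#'                apportion_cell(94, 6))
#' summarize_apportionment(cells)$mean_w  # 92
#' @export
summarize_apportionment <- function(cells) {
  ok <- cells[!cells$excluded, , drop = FALSE]
  if (nrow(ok) == 0L)
    dt_stop("insufficient_data_error", "all apportionment cells are excluded")
  fw <- ok$frac_waterborne
  fd <- ok$frac_dietary
  sdv <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(mean_w = mean(fw), sd_w = sdv(fw), range_w = range(fw),
                 mean_d = mean(fd), sd_d = sdv(fd), range_d = range(fd),
                 ratio = if (mean(fd) > 0) mean(fw) / mean(fd) else Inf,
                 n_cells = nrow(ok), n_excluded = sum(cells$excluded)),
            class = "apportionment_summary")
}

#' @export
print.apportionment_summary <- function(x, ...) {
  cat(sprintf("<apportionment_summary> waterborne %.1f +/- %.1f%% (range %.1f-%.1f%%)\n",
              x$mean_w, x$sd_w, x$range_w[1], x$range_w[2]))
  cat(sprintf("  dietary %.1f +/- %.1f%% (range %.1f-%.1f%%); ratio %.3g; %d cell(s)%s\n",
              x$mean_d, x$sd_d, x$range_d[1], x$range_d[2], x$ratio, x$n_cells,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Bootstrap confidence interval for the mean waterborne share
#'
#' Nonparametric percentile bootstrap: animals are resampled with
#' replacement within each group x day stratum (control strata included, so
#' background-estimation uncertainty propagates), the whole accounting and
#' apportionment pipeline is re-run per replicate, and the 2.5/97.5
#' percentiles of the mean waterborne share are returned.
#'
#' @param table A validated measurement table.
#' @param config An [analysis_config()].
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; identical inputs give identical intervals.
#' @param probs Lower/upper percentile probabilities (default 0.025/0.975).
#' @return A list with `low`, `high`, `point` (mean waterborne share of the
#'   original table), `reps`, and `replicates` (the bootstrap draws that
#'   produced a usable summary).
#' @export
bootstrap_apportionment <- function(table, config, reps = 1000, seed = 1L,
                                    probs = c(0.025, 0.975)) {
  if (reps < 100)
    dt_stop("configuration_error", "bootstrap needs reps >= 100, got %d", reps)
  stopifnot(inherits(config, "analysis_config"))
  point <- suppressWarnings(
    summarize_apportionment(apportion_cells(
      compute_new_accumulation(table, config)))$mean_w)
  strata <- split(seq_len(nrow(table)), paste(table$group, table$day))
  draws <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      boot <- table[idx, , drop = FALSE]
      # resampling can duplicate ids; keys are irrelevant to the arithmetic
      boot$mussel_id <- sprintf("b%06d", seq_len(nrow(boot)))
      tryCatch(suppressWarnings(
        summarize_apportionment(apportion_cells(
          compute_new_accumulation(boot, config)))$mean_w),
        dualtracer_error = function(e) NA_real_)
    }, numeric(1))
  })
  usable <- draws[!is.na(draws)]
  if (length(usable) == 0L)
    dt_stop("insufficient_data_error", "no bootstrap replicate was summarizable")
  ci <- stats::quantile(usable, probs, names = FALSE, type = 7)
  list(low = ci[1L], high = ci[2L], point = point, reps = reps,
       replicates = usable)
}
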