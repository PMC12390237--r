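# Measurement tables.
#
# Internally a measurement table is a plain data.frame with columns
#   group, day, tank, mussel_id, conc_w, conc_d, shell_length_cm, dry_weight_g
# where conc_w / conc_d are the tissue concentrations of the waterborne and
# dietary tracer (ug/g dw).  The on-disk CSV schema names the concentration
# columns after the tracer isotopes (e.g. cd112_ugg_dw, cd113_ugg_dw), so
# files are self-describing; read/write map between the two using the tracer
# labels in the config.

MEAS_INTERNAL_COLS <- c("group", "day", "tank", "mussel_id",
                        "conc_w", "conc_d", "shell_length_cm", "dry_weight_g")

#' Validate a measurement table against a design
#'
#' Enforces the table invariants: required columns present, concentrations
#' non-negative, all groups and days drawn from the design, and no duplicate
#' (group, day, mussel_id) triples.  Every violation names the offending
#' column or row; nothing is dropped silently.
#'
#' @param table A data frame with columns `group`, `day`, `tank`,
#'   `mussel_id`, `conc_w`, `conc_d`, `shell_length_cm`, `dry_weight_g`.
#' @param design An [exposure_design()].
#' @return The validated table (class `measurement_table` prepended),
#'   invisibly usable as a plain data.frame.
#' @export
validate_measurements <- function(table, design) {
  stopifnot(inherits(design, "exposure_design"))
  table <- as.data.frame(table)
  missing <- setdiff(MEAS_INTERNAL_COLS, names(table))
  if (length(missing))
    dt_stop("schema_error", "measurement table is missing column(s): %s",
            paste(missing, collapse = ", "))
  for (col in c("conc_w", "conc_d")) {
    bad <- which(!is.finite(table[[col]]) | table[[col]] < 0)
    if (length(bad))
      dt_stop("validation_error",
              "negative or non-finite %s in row(s) %s", col,
              paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad_day <- which(!table$day %in% design$sample_days)
  if (length(bad_day))
    dt_stop("validation_error",
            "day %s in row %d is not a scheduled sample day (%s)",
            table$day[bad_day[1L]], bad_day[1L],
            paste(design$sample_days, collapse = ", "))
  bad_grp <- which(!table$group %in% design$groups$name)
  if (length(bad_grp))
    dt_stop("validation_error", "unknown group '%s' in row %d",
            table$group[bad_grp[1L]], bad_grp[1L])
  key <- paste(table$group, table$day, table$mussel_id, sep = "\r")
  if (anyDuplicated(key))
    dt_stop("validation_error", "duplicate (group, day, mussel_id) in row %d",
            which(duplicated(key))[1L])
  class(table) <- unique(c("measurement_table", class(table)))
  table
}

#' Read a measurement table from CSV
#'
#' Expects the documented tidy schema: one row per sampled animal, columns
#' `group, day, tank, mussel_id, <w>_ugg_dw, <d>_ugg_dw, shell_length_cm,
#' dry_weight_g`, where `<w>`/`<d>` are the lower-cased tracer labels from
#' `config` (e.g. `cd112_ugg_dw`, `cd113_ugg_dw`).  The result is validated
#' against the design before being returned.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()] (supplies the tracer labels and the
#'   design to validate against).
#' @return A validated measurement table.
#' @export
read_measurements <- function(path, config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!file.exists(path))
    dt_stop("io_error", "measurements file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col_w <- tracer_column(config$tracers$waterborne)
  col_d <- tracer_column(config$tracers$dietary)
  need <- c("group", "day", "tank", "mussel_id", col_w, col_d,
            "shell_length_cm", "dry_weight_g")
  missing <- setdiff(need, names(df))
  if (length(missing))
    dt_stop("schema_error", "CSV is missing column(s): %s",
            paste(missing, collapse = ", "))
  out <- data.frame(group = as.character(df$group),
                    day = as.numeric(df$day),
                    tank = as.character(df$tank),
                    mussel_id = as.character(df$mussel_id),
                    conc_w = as.numeric(df[[col_w]]),
                    conc_d = as.numeric(df[[col_d]]),
                    shell_length_cm = as.numeric(df$shell_length_cm),
                    dry_weight_g = as.numeric(df$dry_weight_g),
                    stringsAsFactors = FALSE)
  validate_measurements(out, config$design)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: values round-trip exactly at full
#' double precision (written with 17 significant digits).
#'
#' @param table A validated measurement table.
#' @param path Output CSV path.
#' @param config An [analysis_config()] (supplies the tracer column names).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, config) {
  stopifnot(inherits(config, "analysis_config"))
  table <- validate_measurements(table, config$design)
  out <- data.frame(group = table$group, day = table$day, tank = table$tank,
                    mussel_id = table$mussel_id, stringsAsFactors = FALSE)
  out[[tracer_column(config$tracers$waterborne)]] <-
    format(table$conc_w, digits = 17, trim = TRUE, scientific = FALSE)
  out[[tracer_column(config$tracers$dietary)]] <-
    format(table$conc_d, digits = 17, trim = TRUE, scientific = FALSE)
  out$shell_length_cm <- format(table$shell_length_cm, digits = 17,
                                trim = TRUE, scientific = FALSE)
  out$dry_weight_g <- format(table$dry_weight_g, digits = 17,
                             trim = TRUE, scientific = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    dt_stop("io_error", "cannot write measurements to %s: %s",
            path, conditionMessage(ok))
  invisible(path)
}
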