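# CSV interchange (RFC-4180, UTF-8, dot decimal). Time is stored in hours,
# concentrations in mM-N, rates in mg N/day/kg soil. Provenance metadata
# travels as '#'-prefixed header lines that base read.csv skips.

TIMESERIES_COLS <- c("treatment", "salinity", "replicate", "time_h",
                     "no2_mM", "no3_mM")
FRACTION_COLS <- c("gradient_id", "condition", "isotope", "replicate",
                   "fraction", "target", "copies")

write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       unlist(provenance, use.names = FALSE)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Coerce a column to numeric, reporting the offending data rows on failure.
numeric_column <- function(x, col, offset = 0) {
  if (is.numeric(x)) return(x)
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "NA")
  if (length(bad) > 0)
    stop("column '", col, "' is not numeric at data row(s) ",
         paste(bad + offset, collapse = ", "), call. = FALSE)
  v
}

#' Read / write microcosm time-series tables
#'
#' The time-series interchange format is a CSV with columns `treatment`
#' (I-IV), `salinity` (percent), `replicate`, `time_h`, `no2_mM`, `no3_mM`.
#' The reader validates the schema (naming offending values and rows),
#' rejects negative concentrations, and returns rows sorted by treatment,
#' salinity, replicate and time.
#'
#' @param path CSV file path.
#' @param df A `treatment_series` data frame to write.
#' @param provenance Optional named list written as `#` header comments.
#' @return `read_timeseries` returns a `treatment_series` data frame.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(TIMESERIES_COLS, names(df))
  if (length(missing) > 0)
    stop("time-series file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_tr <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad_tr) > 0)
    stop("invalid treatment value(s): ", paste(bad_tr, collapse = ", "),
         " (expected I, II, III, IV)", call. = FALSE)
  for (col in c("salinity", "time_h", "no2_mM", "no3_mM"))
    df[[col]] <- numeric_column(df[[col]], col)
  if (any(df$no2_mM < 0, na.rm = TRUE) || any(df$no3_mM < 0, na.rm = TRUE))
    stop("negative concentrations in time-series file", call. = FALSE)
  df <- df[order(df$treatment, df$salinity, df$replicate, df$time_h), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("treatment_series", "data.frame")
  df
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(df, path, provenance = NULL) {
  stopifnot(all(TIMESERIES_COLS %in% names(df)))
  write_csv_provenance(as.data.frame(df)[TIMESERIES_COLS], path, provenance)
}

#' Read / write SIP fraction tables
#'
#' Long-format CSV with columns `gradient_id`, `condition`, `isotope`
#' (12C/13C), `replicate`, `fraction`, `target`, `copies`, and either
#' `density` (g/mL) or `ri` (refractive index, converted on load with the
#' supplied calibration). Fractions may arrive in any order; rows are
#' sorted so that fraction 1 is heaviest, preserving the heavy = low-index
#' numbering.
#'
#' @param path CSV file path.
#' @param calibration Refractive-index calibration used when the file has
#'   an `ri` column instead of `density` (see [fit_ri_calibration()]).
#' @param df A `fraction_table` data frame to write.
#' @param provenance Optional named list written as `#` header comments.
#' @return `read_fraction_table` returns a `fraction_table` data frame.
#' @export
read_fraction_table <- function(path, calibration = default_ri_calibration()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(FRACTION_COLS, names(df))
  if (length(missing) > 0)
    stop("fraction file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"density" %in% names(df)) {
    if (!"ri" %in% names(df))
      stop("fraction file needs a density or ri column", call. = FALSE)
    df$ri <- numeric_column(df$ri, "ri")
    df$density <- ri_to_density(df$ri, calibration)
  }
  for (col in c("fraction", "density", "copies"))
    df[[col]] <- numeric_column(df[[col]], col)
  if (any(df$copies < 0, na.rm = TRUE))
    stop("negative copy numbers in fraction file", call. = FALSE)
  bad_iso <- setdiff(unique(df$isotope), c("12C", "13C"))
  if (length(bad_iso) > 0)
    stop("invalid isotope value(s): ", paste(bad_iso, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$gradient_id, df$isotope, df$replicate, df$target,
                 df$fraction), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fraction_table", "data.frame")
  df
}

#' @rdname read_fraction_table
#' @export
write_fraction_table <- function(df, path, provenance = NULL) {
  cols <- c(FRACTION_COLS[1:5], "density", FRACTION_COLS[6:7])
  stopifnot(all(cols %in% names(df)))
  write_csv_provenance(as.data.frame(df)[cols], path, provenance)
}

#' Read a qPCR Cq table
#'
#' CSV with columns `target`, `sample`, `cq`, `role` (`standard` or
#' `unknown`) and, for standards, `log10_copies`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("target", "sample", "cq", "role")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("qPCR file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(df$role), c("standard", "unknown"))
  if (length(bad_role) > 0)
    stop("invalid role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  df$cq <- numeric_column(df$cq, "cq")
  if (!"log10_copies" %in% names(df)) df$log10_copies <- NA_real_
  df$log10_copies <- numeric_column(df$log10_copies, "log10_copies")
  if (any(df$role == "standard" & is.na(df$log10_copies)))
    stop("standards must carry log10_copies", call. = FALSE)
  df
}
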