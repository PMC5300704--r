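#' Read and write growth traces, rate tables and cost surfaces as CSV
#'
#' All files are plain CSV with mandatory headers and units embedded in the
#' column names.  Traces use `time_s, length_nm[, n_monomers, occupancy]`;
#' rate tables use `length_nm, rate_nm_per_min, interval_min`; cost surfaces
#' use `D_nm2_s, LS, cost` (flagged cells written as `NA`).
#'
#' @param path File path.
#' @param trace,curve,data,result Object to write.
#' @return Readers return the corresponding object; writers return the path
#'   invisibly.
#' @name flagrowth_io
NULL

.check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
}

#' @rdname flagrowth_io
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop(path, ": no such file")
  if (file.size(path) == 0L) {
    warning(path, ": empty file; empty trace")
    return(structure(data.frame(time_s = numeric(0), length_nm = numeric(0)),
                     class = c("growth_trace", "data.frame")))
  }
  df <- tryCatch(read.csv(path, check.names = TRUE),
                 error = function(e) stop(path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) {
    warning(path, ": no data rows; empty trace")
    df <- data.frame(time_s = numeric(0), length_nm = numeric(0))
  } else {
    .check_columns(df, c("time_s", "length_nm"), path)
    df$time_s <- suppressWarnings(as.numeric(df$time_s))
    df$length_nm <- suppressWarnings(as.numeric(df$length_nm))
    bad <- which(!is.finite(df$time_s) | !is.finite(df$length_nm))
    if (length(bad))
      stop(sprintf("%s: malformed row at line %d", path, bad[1L] + 1L))
  }
  structure(df, class = c("growth_trace", "data.frame"))
}

#' @rdname flagrowth_io
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname flagrowth_io
#' @export
read_rate_csv <- function(path) {
  df <- read.csv(path)
  if (nrow(df) == 0L) {
    warning(path, ": no data rows")
    return(rate_curve(numeric(0), numeric(0)))
  }
  .check_columns(df, c("length_nm", "rate_nm_per_min"), path)
  iv <- if ("interval_min" %in% names(df)) df$interval_min[1L] else NA_real_
  rate_curve(df$length_nm, df$rate_nm_per_min, iv)
}

#' @rdname flagrowth_io
#' @export
write_rate_csv <- function(curve, path) {
  df <- data.frame(length_nm = curve$length_nm,
                   rate_nm_per_min = curve$rate_nm_per_min,
                   interval_min = rep_len(attr(curve, "interval_min"),
                                          nrow(curve)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname flagrowth_io
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("length_nm", "rate_nm_per_min", "interval_min"), path)
  growth_rate_data(df$length_nm, df$rate_nm_per_min, df$interval_min)
}

#' @rdname flagrowth_io
#' @export
write_dataset_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname flagrowth_io
#' @export
write_contour_csv <- function(result, path) {
  surf <- if (inherits(result, "idm_fit")) result$surface else result
  write.csv(surf[, c("D_nm2_s", "LS", "cost")], path, row.names = FALSE,
            quote = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname flagrowth_io
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("D_nm2_s", "LS", "cost"), path)
  df
}
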