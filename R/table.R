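MEASUREMENT_COLS <- c("subject_id", "group", "session", "muscle", "side",
                      "metric", "value")
MEASUREMENT_GROUPS <- c("patient", "control")
MEASUREMENT_SESSIONS <- c("baseline", "week1", "month9", "month18")
MEASUREMENT_SIDES <- c("left", "right")
MEASUREMENT_METRICS <- c("stiffness_kPa", "pdff_fraction", "volume_cc")

#' Long-format measurement table
#'
#' One row per (subject, session, muscle, side, metric) observation; the
#' carrier for all reliability and longitudinal statistics. Values are
#' numeric and finite, or `NA` for explicitly missing measurements.
#'
#' @param df data frame with columns `subject_id`, `group` (patient/control),
#'   `session` (baseline/week1/month9/month18), `muscle`, `side`
#'   (left/right), `metric` (stiffness_kPa/pdff_fraction/volume_cc), `value`.
#' @return A validated data frame of class `measurement_table`.
#' @export
measurement_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(miss))
    stop("measurement table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[MEASUREMENT_COLS]
  check_levels <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  if (nrow(df)) {
    check_levels("group", MEASUREMENT_GROUPS)
    check_levels("session", MEASUREMENT_SESSIONS)
    check_levels("side", MEASUREMENT_SIDES)
    check_levels("metric", MEASUREMENT_METRICS)
  }
  df$value <- as.numeric(df$value)
  if (any(is.infinite(df$value)))
    stop("values must be finite or NA")
  key <- do.call(paste, c(df[c("subject_id", "session", "muscle", "side",
                               "metric")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate measurement key at row ", dup[1], ": ",
         gsub("\r", " / ", key[dup[1]]))
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read/write a measurement table as CSV
#'
#' CSV round-trips are lossless for finite values; missing values are
#' encoded as empty cells.
#'
#' @param path CSV path; the header must carry the seven field names.
#' @return A [measurement_table] (read) or `path`, invisibly (write).
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(value = "numeric"))
  measurement_table(df)
}

#' @param table a [measurement_table] (or coercible data frame).
#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(table, path) {
  table <- measurement_table(table)
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
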