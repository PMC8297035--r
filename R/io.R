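#' Read a station table from delimited text
#'
#' The station-table layout is comma-separated with a header:
#' `station_id, u, v, y`, one column per feature, and a `<feature>__var`
#' column carrying each feature's measurement variance. An optional `date`
#' column is carried through but ignored by the estimators.
#'
#' @param path path to a CSV file.
#' @param var_default global measurement variance used for features lacking
#'   a `__var` column; `NULL` (default) makes a missing `__var` column an
#'   error at system-assembly time (reading still succeeds).
#' @return validated data frame with attribute `"features"`.
#' @export
read_station_table <- function(path, var_default = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("station_id", "u", "v", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("station table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("u", "v", "y")) {
    if (!is.numeric(data[[col]]))
      stop("column '", col, "' must be numeric")
  }
  features <- setdiff(names(data), c(required, "date"))
  features <- features[!grepl("__var$", features)]
  for (f in features) {
    vc <- paste0(f, "__var")
    if (!vc %in% names(data) && is.null(var_default))
      stop("feature '", f, "' has no '", vc,
           "' variance column and no var_default is configured")
    if (vc %in% names(data) && any(data[[vc]] < 0)) {
      bad <- which(data[[vc]] < 0)
      stop("negative variance in column '", vc, "' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  message("read ", nrow(data), " rows, ", length(unique(data$station_id)),
          " stations, ", length(features), " features from ", path)
  attr(data, "features") <- features
  data
}

#' Write a station table (or any data frame) as delimited text
#'
#' @param data data frame.
#' @param path output path.
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments before the table.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(data, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
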