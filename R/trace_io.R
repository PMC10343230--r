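#' Write a trace to CSV
#'
#' One metadata header line (`# kind=...; units=...; key=value; ...`)
#' followed by a `time_min,value` table. Comma-separated, UTF-8, decimal
#' points — simple and grep-able. Scalar metadata entries are carried in
#' the header line; the round trip `read_trace_csv(write_trace_csv(x))` is
#' lossless to text precision.
#'
#' @param trace an [o2_trace()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  meta <- trace$meta[vapply(trace$meta, function(v)
    is.atomic(v) && length(v) == 1L && !is.na(v), logical(1))]
  fields <- c(kind = trace$kind, units = trace_units(trace$kind),
              vapply(meta, function(v) format(v, digits = 17),
                     character(1)))
  header <- paste0("# ", paste(names(fields), fields, sep = "=",
                               collapse = "; "))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("time_min,value", con)
  writeLines(paste(format(trace$time_min, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(trace$value, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Parses the metadata header written by [write_trace_csv()]; the `kind`
#' field is mandatory. Time must be strictly increasing — a duplicate or
#' backward timestamp is reported with its row index.
#'
#' @param path CSV file path.
#' @return an [o2_trace()]; header metadata (numeric where possible) in
#'   `meta`.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L)
    stop("trace CSV too short: ", path)
  if (!startsWith(lines[1], "#"))
    stop("missing metadata header line (expected '# kind=...'): ", path)
  kv <- strsplit(trimws(sub("^#", "", lines[1])), ";[ ]*")[[1]]
  kv <- kv[nzchar(kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- as.list(vals)
  names(meta) <- trimws(keys)
  num <- suppressWarnings(as.numeric(vals))
  meta[!is.na(num)] <- as.list(num[!is.na(num)])
  if (is.null(meta$kind))
    stop("metadata header lacks the mandatory 'kind' field: ", path)
  kind <- meta$kind
  meta$kind <- NULL
  meta$units <- NULL

  df <- read.csv(textConnection(lines[-1]))
  if (!all(c("time_min", "value") %in% names(df)))
    stop("trace CSV needs columns time_min,value: ", path)
  if (anyNA(df$time_min) || anyNA(df$value))
    stop("non-numeric or missing cells in trace CSV: ", path)
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad))
    stop(sprintf(
      "time column not strictly increasing at data row %d (t = %g): %s",
      bad[1] + 1L, df$time_min[bad[1] + 1L], path))
  o2_trace(df$time_min, df$value, kind = kind, meta = meta)
}
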