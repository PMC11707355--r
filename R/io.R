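# Plain-text readers/writers for scans, score tables and acquisition tables.
#
# csv_wide scan layout: first row "wavenumber,<w1>,<w2>,..."; one row per
# pixel "px_<r>_<c>,<i1>,...".  JSON mirrors the hyper_scan fields.  Values
# are serialized at full double precision so write -> read is bit-exact.

#' Write a hyperspectral scan to CSV or JSON
#'
#' @param scan A [hyper_scan()].
#' @param path Output file path.
#' @param format `"csv_wide"` or `"json"`.
#' @return Invisibly, `path`.
#' @seealso [read_scan()]
#' @export
write_scan <- function(scan, path, format = c("csv_wide", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(scan, "hyper_scan"))
  if (nrow(scan$pixels) == 0L) stop("refusing to write an empty scan", call. = FALSE)
  if (format == "csv_wide") {
    rows <- character(nrow(scan$pixels) + 1L)
    rows[1] <- paste(c("wavenumber", fmt_num(scan$wavenumber)), collapse = ",")
    ids <- sprintf("px_%d_%d",
                   rep(seq_len(scan$n_rows), each = scan$n_cols),
                   rep(seq_len(scan$n_cols), times = scan$n_rows))
    for (i in seq_len(nrow(scan$pixels)))
      rows[i + 1L] <- paste(c(ids[i], fmt_num(scan$pixels[i, ])), collapse = ",")
    con <- file(path, "wb")  # binary mode: stable newlines across platforms
    on.exit(close(con))
    writeLines(c(sprintf("# roi=%s protocol=%s rows=%d cols=%d", scan$roi,
                         ifelse(is.na(scan$protocol), "NA", scan$protocol),
                         scan$n_rows, scan$n_cols),
                 rows), con, sep = "\n")
  } else {
    obj <- list(wavenumber = scan$wavenumber,
                grid_shape = c(scan$n_rows, scan$n_cols),
                roi = scan$roi,
                protocol = if (is.na(scan$protocol)) NULL else scan$protocol,
                pixels = scan$pixels)
    # I(17) significant digits: doubles survive the round-trip bit-exactly
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a hyperspectral scan from CSV or JSON
#'
#' @param path Input file written by [write_scan()] (or following the same
#'   layout).
#' @param format `"csv_wide"` or `"json"`.
#' @return A validated [hyper_scan()].
#' @export
read_scan <- function(path, format = c("csv_wide", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv_wide") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1], "# roi="))
      stop("malformed scan header", call. = FALSE)
    hdr <- regmatches(lines[1],
                      regexec("^# roi=(\\S+) protocol=(\\S+) rows=(\\d+) cols=(\\d+)$",
                              lines[1]))[[1]]
    if (length(hdr) != 5L) stop("malformed scan header", call. = FALSE)
    axis_fields <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    if (axis_fields[1] != "wavenumber") stop("malformed axis row", call. = FALSE)
    wavenumber <- as.numeric(axis_fields[-1])
    if (anyDuplicated(wavenumber) || any(diff(wavenumber) <= 0))
      stop("wavenumber axis must be strictly increasing (duplicated or unsorted columns)",
           call. = FALSE)
    body <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
    pixels <- t(vapply(body, function(f) as.numeric(f[-1]),
                       numeric(length(wavenumber))))
    hyper_scan(wavenumber, pixels,
               n_rows = as.integer(hdr[4]), n_cols = as.integer(hdr[5]),
               roi = hdr[2],
               protocol = if (hdr[3] == "NA") NA_character_ else hdr[3])
  } else {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$wavenumber) || is.null(obj$pixels) || is.null(obj$grid_shape))
      stop("malformed scan JSON: missing fields", call. = FALSE)
    if (anyDuplicated(obj$wavenumber))
      stop("wavenumber axis must be strictly increasing", call. = FALSE)
    hyper_scan(obj$wavenumber, obj$pixels,
               n_rows = obj$grid_shape[1], n_cols = obj$grid_shape[2],
               roi = obj$roi,
               protocol = if (is.null(obj$protocol)) NA_character_ else obj$protocol)
  }
}

#' Read an observer score table from CSV
#'
#' Expects a one-line header with columns
#' `modality,protocol,batch,observer,parameter,score`.
#'
#' @param path CSV file path.
#' @return A validated [score_table()].
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_table(df)
}

#' Write an observer score table to CSV
#'
#' @param table A [score_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  table <- score_table(table)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("modality,protocol,batch,observer,parameter,score",
               sprintf("%s,%s,%d,%s,%s,%d", table$modality, table$protocol,
                       table$batch, table$observer, table$parameter,
                       table$score)), con, sep = "\n")
  invisible(path)
}

#' Read fluorescence acquisition settings from CSV
#'
#' One row per (protocol, batch, channel) with the laser power (instrument %)
#' and detector gain used during image acquisition.
#'
#' @param path CSV with columns `protocol,batch,channel,laser_power,detector_gain`.
#' @return A data frame with validated columns.
#' @export
read_acquisition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("protocol", "batch", "channel", "laser_power", "detector_gain")
  if (!all(required %in% names(df)))
    stop("acquisition table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  for (p in unique(df$protocol)) parse_protocol(p)
  if (any(df$laser_power <= 0) || any(df$detector_gain <= 0))
    stop("laser_power and detector_gain must be positive", call. = FALSE)
  df$batch <- as.integer(df$batch)
  df[required]
}

#' @rdname read_acquisition_table
#' @param table Acquisition data frame.
#' @export
write_acquisition_table <- function(table, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("protocol,batch,channel,laser_power,detector_gain",
               sprintf("%s,%d,%s,%s,%s", table$protocol, as.integer(table$batch),
                       table$channel, fmt_num(table$laser_power),
                       fmt_num(table$detector_gain))), con, sep = "\n")
  invisible(path)
}
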