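# Plain-text I/O: TSV traces and distance distributions, CSV dose-response
# tables. Floats are written with 17 significant digits so write -> read
# round-trips are bit-exact; metadata travels in '#'-prefixed header lines.

fmt17 <- function(x) sprintf("%.17g", x)

write_meta_header <- function(con, meta) {
  meta <- meta[!vapply(meta, is.list, logical(1))]  # flat fields only
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
}

read_meta_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

parse_numeric_table <- function(path, sep, required_cols) {
  lines <- readLines(path)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop_input("file ", path, " has no data")
  header_line <- lines[body_idx[1]]
  cols <- trimws(strsplit(header_line, sep, fixed = TRUE)[[1]])
  missing <- setdiff(required_cols, cols)
  if (length(missing)) {
    stop_input("file ", path, " is missing column(s): ",
               paste(missing, collapse = ", "))
  }
  rows <- body_idx[-1]
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(NULL, cols))
  blank_cells <- logical(length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[i]
    fields <- trimws(strsplit(lines[ln], sep, fixed = TRUE)[[1]])
    if (length(fields) < length(cols)) {
      fields <- c(fields, rep("", length(cols) - length(fields)))
    }
    blank_cells[i] <- any(!nzchar(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals) & nzchar(fields))) {
      stop_input("parse error in ", path, " at line ", ln,
                 ": non-numeric field")
    }
    out[i, ] <- vals[seq_len(length(cols))]
  }
  list(data = as.data.frame(out), meta = read_meta_header(lines),
       blank = blank_cells)
}

#' Write / read a DEER trace as TSV
#'
#' Tab-separated columns `time_us` and `signal`; flat metadata fields are
#' stored in `#`-prefixed header comments and restored on read. Values are
#' serialized with 17 significant digits, so a write -> read round trip is
#' bit-exact for finite values.
#'
#' @param trace a `deer_trace`.
#' @param path file path.
#' @return `write_deer_trace` returns `path` invisibly; `read_deer_trace`
#'   returns a `deer_trace`.
#' @export
write_deer_trace <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  con <- file(path, "w"); on.exit(close(con))
  write_meta_header(con, trace$meta)
  writeLines("time_us\tsignal", con)
  writeLines(paste(fmt17(trace$t), fmt17(trace$v), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_deer_trace
#' @export
read_deer_trace <- function(path) {
  parsed <- parse_numeric_table(path, "\t", c("time_us", "signal"))
  d <- parsed$data
  if (is.unsorted(d$time_us, strictly = TRUE)) {
    stop_input("non-monotone time axis in ", path)
  }
  deer_trace(d$time_us, d$signal, meta = parsed$meta)
}

#' Write / read a distance distribution as TSV
#'
#' Columns `r_nm` and `density`; same conventions as [write_deer_trace()].
#'
#' @param dist a `distance_distribution`.
#' @param path file path.
#' @export
write_distance_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("r_nm\tdensity", con)
  writeLines(paste(fmt17(dist$r), fmt17(dist$density), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_distribution
#' @export
read_distance_distribution <- function(path) {
  parsed <- parse_numeric_table(path, "\t", c("r_nm", "density"))
  distance_distribution(parsed$data$r_nm, parsed$data$density,
                        normalize = FALSE)
}

#' Read a dose-response CSV
#'
#' Comma-separated columns `conc_uM`, `activity`, `sd`. Negative
#' concentrations are rejected; blank `sd` cells become 0 with a warning.
#'
#' @param path file path.
#' @return a `dose_response`.
#' @export
read_dose_response <- function(path) {
  parsed <- parse_numeric_table(path, ",", c("conc_uM", "activity", "sd"))
  d <- parsed$data
  if (any(is.na(d$sd))) {
    warning("blank sd values in ", path, "; set to 0", call. = FALSE)
    d$sd[is.na(d$sd)] <- 0
  }
  if (any(is.na(d$conc_uM)) || any(is.na(d$activity))) {
    stop_input("missing conc_uM or activity values in ", path)
  }
  dose_response(d$conc_uM, d$activity, d$sd)
}

#' Write a dose-response CSV
#'
#' @param data a `dose_response`.
#' @param path file path.
#' @export
write_dose_response <- function(data, path) {
  stopifnot(inherits(data, "dose_response"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("conc_uM,activity,sd", con)
  writeLines(paste(fmt17(data$conc_uM), fmt17(data$activity),
                   fmt17(data$sd), sep = ","), con)
  invisible(path)
}
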