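# Data-logger text format: one record per line, `key=value` pairs separated
# by `;`, record type first (`rec=hdr|acc|aux|gnss|ann`). The header carries
# the sampling frequency `f` plus free-form date/device strings; sample
# timestamps are implicit (index / f), all other record times are seconds
# from trace start. Accelerations are serialized at 6 significant digits.

#' Construct a logger trace
#'
#' A `logger_trace` bundles one recording of the transport data logger: the
#' tri-axial acceleration samples, optional auxiliary sensor channels
#' (temperature, air pressure, light, relative humidity), GNSS fixes, and
#' speed / road-surface / event annotations.
#'
#' @param f Sampling frequency in Hz (positive integer).
#' @param samples Data frame with columns `index` (0-based, strictly
#'   increasing integer), `ax`, `ay`, `az` (acceleration per axis, logger
#'   units; the default interpretation is g). A matrix with three columns is
#'   accepted and gains a 0-based index.
#' @param aux Optional data frame with columns `time` (s from trace start),
#'   `channel` (e.g. `"temperature"`), `value`.
#' @param gnss Optional data frame with columns `time` (s), `lat`, `lon`
#'   (decimal degrees) and optionally `elevation` (m).
#' @param annotations Optional data frame with columns `time` (s), `kind`
#'   (one of `"speed"`, `"road_surface"`, `"event"`), `value` (character;
#'   km/h for speed, surface label A--D, free text for events).
#' @param meta Named list of header strings; `date` and `device` are written
#'   to the log header.
#'
#' @return An object of class `logger_trace`.
#' @seealso [read_log()], [write_log()], [displacement_series()]
#' @export
#' @examples
#' acc <- matrix(rnorm(300), ncol = 3)
#' tr <- logger_trace(f = 50, samples = acc)
#' trace_duration(tr)
logger_trace <- function(f, samples, aux = NULL, gnss = NULL,
                         annotations = NULL, meta = list()) {
  if (is.matrix(samples)) {
    stopifnot(ncol(samples) == 3)
    samples <- tibble::tibble(
      index = seq_len(nrow(samples)) - 1L,
      ax = samples[, 1], ay = samples[, 2], az = samples[, 3]
    )
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0 && !all(c("index", "ax", "ay", "az") %in% names(samples))) {
    samples <- tibble::tibble(index = integer(), ax = double(),
                              ay = double(), az = double())
  }
  trace <- structure(
    list(
      f = as.integer(f),
      samples = samples,
      aux = empty_if_null(aux, c("time", "channel", "value"),
                          list(double(), character(), double())),
      gnss = empty_if_null(gnss, c("time", "lat", "lon", "elevation"),
                           list(double(), double(), double(), double())),
      annotations = empty_if_null(annotations, c("time", "kind", "value"),
                                  list(double(), character(), character())),
      meta = meta
    ),
    class = "logger_trace"
  )
  trace$annotations$value <- as.character(trace$annotations$value)
  validate_logger_trace(trace)
  trace
}

empty_if_null <- function(x, cols, prototypes) {
  if (is.null(x)) {
    names(prototypes) <- cols
    return(tibble::as_tibble(prototypes))
  }
  x <- tibble::as_tibble(x)
  if (!"elevation" %in% names(x) && "lat" %in% cols) x$elevation <- NA_real_
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x[cols]
}

validate_logger_trace <- function(trace) {
  stopifnot(inherits(trace, "logger_trace"))
  if (is.na(trace$f) || trace$f <= 0) {
    stop("sampling frequency `f` must be a positive integer", call. = FALSE)
  }
  s <- trace$samples
  if (nrow(s) > 0) {
    if (!all(is.finite(s$ax) & is.finite(s$ay) & is.finite(s$az))) {
      stop("acceleration samples must be finite", call. = FALSE)
    }
    if (any(diff(s$index) <= 0)) {
      stop("sample indices must be strictly increasing", call. = FALSE)
    }
  }
  dur <- trace_duration(trace)
  g <- trace$gnss
  if (nrow(g) > 0) {
    if (any(g$lat < -90 | g$lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
    if (any(g$lon < -180 | g$lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
    if (is.unsorted(g$time)) stop("GNSS fix times must be non-decreasing", call. = FALSE)
    if (any(g$time > dur + 1e-9)) stop("GNSS fix time exceeds trace duration", call. = FALSE)
  }
  a <- trace$annotations
  if (nrow(a) > 0) {
    if (!all(a$kind %in% c("speed", "road_surface", "event"))) {
      stop("annotation kind must be speed, road_surface or event", call. = FALSE)
    }
    if (any(a$time > dur + 1e-9)) stop("annotation time exceeds trace duration", call. = FALSE)
    spd <- suppressWarnings(as.numeric(a$value[a$kind == "speed"]))
    if (anyNA(spd) || any(spd < 0)) {
      stop("speed annotations must be non-negative numbers", call. = FALSE)
    }
  }
  invisible(trace)
}

#' @rdname logger_trace
#' @param trace A `logger_trace`.
#' @return `trace_duration()`: recording length in seconds
#'   (`nrow(samples) / f`).
#' @export
trace_duration <- function(trace) {
  nrow(trace$samples) / trace$f
}

#' @export
print.logger_trace <- function(x, ...) {
  cat(sprintf(
    "<logger_trace> %d samples @ %d Hz (%.1f s), %d aux, %d gnss, %d annotations\n",
    nrow(x$samples), x$f, trace_duration(x), nrow(x$aux), nrow(x$gnss),
    nrow(x$annotations)
  ))
  invisible(x)
}

# 6 significant digits for accelerations, 10 elsewhere; %g keeps the file
# compact and bit-stable on re-write.
fmt_acc <- function(x) sprintf("%.6g", x)
fmt_num <- function(x) sprintf("%.10g", x)

check_field_text <- function(x) {
  bad <- grepl("[;=\n]", x)
  if (any(bad)) {
    stop("field values may not contain ';', '=' or newlines: ",
         x[bad][1], call. = FALSE)
  }
  x
}

#' Write a logger trace to the data-logger text format
#'
#' The format is UTF-8 text with one record per line as `key=value` pairs
#' separated by `;`; the first pair names the record type
#' (`rec=hdr|acc|aux|gnss|ann`). Writing the same trace twice produces
#' byte-identical files, and a written file reads back losslessly at the
#' serialized precision (6 significant digits for accelerations).
#'
#' @param trace A valid [logger_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(trace, path) {
  validate_logger_trace(trace)
  lines <- character(0)
  meta_date <- if (!is.null(trace$meta$date)) trace$meta$date else ""
  meta_dev <- if (!is.null(trace$meta$device)) trace$meta$device else ""
  check_field_text(c(meta_date, meta_dev))
  lines <- c(lines, sprintf("rec=hdr;f=%d;date=%s;device=%s",
                            trace$f, meta_date, meta_dev))
  s <- trace$samples
  if (nrow(s) > 0) {
    lines <- c(lines, sprintf("rec=acc;i=%d;ax=%s;ay=%s;az=%s",
                              as.integer(s$index),
                              fmt_acc(s$ax), fmt_acc(s$ay), fmt_acc(s$az)))
  }
  x <- trace$aux
  if (nrow(x) > 0) {
    check_field_text(x$channel)
    lines <- c(lines, sprintf("rec=aux;t=%s;ch=%s;v=%s",
                              fmt_num(x$time), x$channel, fmt_num(x$value)))
  }
  g <- trace$gnss
  if (nrow(g) > 0) {
    ele <- ifelse(is.na(g$elevation), "", sprintf(";ele=%s", fmt_num(g$elevation)))
    lines <- c(lines, sprintf("rec=gnss;t=%s;lat=%s;lon=%s%s",
                              fmt_num(g$time), fmt_num(g$lat), fmt_num(g$lon), ele))
  }
  a <- trace$annotations
  if (nrow(a) > 0) {
    check_field_text(a$value)
    lines <- c(lines, sprintf("rec=ann;t=%s;kind=%s;value=%s",
                              fmt_num(a$time), a$kind, a$value))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

parse_record <- function(line, lineno) {
  parts <- strsplit(line, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) if (length(p) >= 2) p[2] else "", "")
  names(vals) <- keys
  vals
}

req_num <- function(rec, key, lineno, what) {
  if (!key %in% names(rec)) {
    stop(sprintf("line %d: missing %s field '%s'", lineno, what, key),
         call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(rec[[key]]))
  if (is.na(v) && rec[[key]] != "NA") {
    stop(sprintf("line %d: non-numeric value for '%s': '%s'",
                 lineno, key, rec[[key]]), call. = FALSE)
  }
  v
}

#' Read a data-logger text file
#'
#' Parses the key-value logger format written by [write_log()] and returns a
#' validated [logger_trace()].
#'
#' @param path Path to a logger text file.
#' @return A `logger_trace`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty log file: ", path, call. = FALSE)
  recs <- lapply(seq_along(lines), function(i) parse_record(lines[i], i))
  types <- vapply(recs, function(r) r[["rec"]][1], "")
  hdr_idx <- which(types == "hdr")
  if (length(hdr_idx) == 0) {
    stop("format error: no header record (rec=hdr)", call. = FALSE)
  }
  hdr <- recs[[hdr_idx[1]]]
  if (!"f" %in% names(hdr)) {
    stop("format error: header is missing key 'f'", call. = FALSE)
  }
  f <- req_num(hdr, "f", hdr_idx[1], "header")

  acc_i <- which(types == "acc")
  samples <- if (length(acc_i) > 0) {
    tibble::tibble(
      index = vapply(acc_i, function(i) req_num(recs[[i]], "i", i, "acceleration"), 0),
      ax = vapply(acc_i, function(i) req_num(recs[[i]], "ax", i, "acceleration"), 0),
      ay = vapply(acc_i, function(i) req_num(recs[[i]], "ay", i, "acceleration"), 0),
      az = vapply(acc_i, function(i) req_num(recs[[i]], "az", i, "acceleration"), 0)
    )
  } else NULL
  if (!is.null(samples) && any(diff(samples$index) <= 0)) {
    stop("integrity error: sample indices are not strictly increasing",
         call. = FALSE)
  }

  aux_i <- which(types == "aux")
  aux <- if (length(aux_i) > 0) {
    tibble::tibble(
      time = vapply(aux_i, function(i) req_num(recs[[i]], "t", i, "aux"), 0),
      channel = vapply(aux_i, function(i) recs[[i]][["ch"]], ""),
      value = vapply(aux_i, function(i) req_num(recs[[i]], "v", i, "aux"), 0)
    )
  } else NULL

  gnss_i <- which(types == "gnss")
  gnss <- if (length(gnss_i) > 0) {
    tibble::tibble(
      time = vapply(gnss_i, function(i) req_num(recs[[i]], "t", i, "gnss"), 0),
      lat = vapply(gnss_i, function(i) req_num(recs[[i]], "lat", i, "gnss"), 0),
      lon = vapply(gnss_i, function(i) req_num(recs[[i]], "lon", i, "gnss"), 0),
      elevation = vapply(gnss_i, function(i) {
        if ("ele" %in% names(recs[[i]])) req_num(recs[[i]], "ele", i, "gnss") else NA_real_
      }, 0)
    )
  } else NULL

  ann_i <- which(types == "ann")
  annotations <- if (length(ann_i) > 0) {
    tibble::tibble(
      time = vapply(ann_i, function(i) req_num(recs[[i]], "t", i, "annotation"), 0),
      kind = vapply(ann_i, function(i) recs[[i]][["kind"]], ""),
      value = vapply(ann_i, function(i) recs[[i]][["value"]], "")
    )
  } else NULL

  meta <- list()
  if ("date" %in% names(hdr) && nzchar(hdr[["date"]])) meta$date <- hdr[["date"]]
  if ("device" %in% names(hdr) && nzchar(hdr[["device"]])) meta$device <- hdr[["device"]]

  logger_trace(f = f, samples = samples %||% tibble::tibble(
    index = integer(), ax = double(), ay = double(), az = double()
  ), aux = aux, gnss = gnss, annotations = annotations, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a displacement series to CSV
#'
#' Writes one row per second with columns `second_index` (0-based) and `di`.
#'
#' @param series A [displacement_series] object (or bare numeric vector of
#'   per-second index values).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_series_csv <- function(series, path) {
  values <- di_values(series)
  df <- tibble::tibble(second_index = seq_along(values) - 1L, di = values)
  readr::write_csv(df, path)
  invisible(path)
}

#' Export a trace's GNSS track as GPX 1.1
#'
#' Writes a single `<trk>` with one `<trkseg>` holding all fixes in order;
#' a trace without fixes yields an empty track segment.
#'
#' @param trace A [logger_trace()].
#' @param path Output GPX path.
#' @param name Track name written into the file.
#' @return `path`, invisibly.
#' @export
export_track_gpx <- function(trace, path, name = "roadvib track") {
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "roadvib",
    xmlns = "http://www.topografix.com/GPX/1/1"
  )
  trk <- xml2::xml_add_child(doc, "trk")
  xml2::xml_add_child(trk, "name", name)
  seg <- xml2::xml_add_child(trk, "trkseg")
  g <- trace$gnss
  for (i in seq_len(nrow(g))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = fmt_num(g$lat[i]), lon = fmt_num(g$lon[i]))
    if (!is.na(g$elevation[i])) {
      xml2::xml_add_child(pt, "ele", fmt_num(g$elevation[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
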