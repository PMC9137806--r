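# Field-delivery analysis: whole-trip summary, intensity distribution,
# quality-class proportions, and run-length detection of high-vibration
# road stretches with optional GNSS geolocation.

#' Summarize a field delivery
#'
#' Whole-trip view of a delivery's vibration exposure: overall mean index,
#' the binned per-second intensity distribution (default bins `<=1`,
#' `>1-2`, ..., `>5`), and the share of trip time per road-quality class
#' ([classify_quality()]).
#'
#' @param series Non-empty [displacement_series] of the trip.
#' @param edges Bin boundaries for [bin_distribution()].
#' @return A `delivery_report`: list with `duration_s`, `overall_dbar`,
#'   `distribution` (tibble), `quality` (tibble of class, seconds, pct) and
#'   a `segments` slot (`NULL` until [detect_segments()] output is
#'   attached).
#' @export
delivery_summary <- function(series, edges = default_bin_edges) {
  values <- di_values(series)
  if (length(values) == 0) stop("empty displacement series", call. = FALSE)
  quality <- table(classify_quality(values))
  structure(
    list(
      duration_s = length(values),
      overall_dbar = trial_mean(values),
      distribution = bin_distribution(values, edges),
      quality = tibble::tibble(
        class = names(quality),
        seconds = as.integer(quality),
        pct = as.integer(quality) / length(values) * 100
      ),
      segments = NULL
    ),
    class = "delivery_report"
  )
}

#' @export
print.delivery_report <- function(x, ...) {
  cat(sprintf("<delivery_report> %.1f min, overall mean Di %.2f\n",
              x$duration_s / 60, x$overall_dbar))
  cat(sprintf("  quality: %s\n",
              paste(sprintf("%s %.1f%%", x$quality$class, x$quality$pct),
                    collapse = ", ")))
  if (!is.null(x$segments)) {
    cat(sprintf("  %d high-vibration segment(s)\n", nrow(x$segments)))
  }
  invisible(x)
}

#' Detect high-vibration road segments
#'
#' Finds maximal runs of consecutive seconds whose Displacement Index
#' strictly exceeds `threshold` (e.g. the access-road criterion
#' \eqn{D_i > 3}) and keeps runs of at least `min_duration` seconds. Runs
#' separated by at most `gap_tolerance` below-threshold seconds are merged
#' before the duration filter.
#'
#' @param series [displacement_series] or numeric per-second values.
#' @param threshold Index value a second must exceed (strict `>`).
#' @param min_duration Minimum segment length in seconds (>= 1).
#' @param gap_tolerance Below-threshold seconds allowed inside a segment.
#' @return Tibble of non-overlapping, ordered segments: `start_s`, `end_s`
#'   (half-open `[start_s, end_s)` in trip time), `duration_s`, `mean_di`,
#'   `peak_di`, `threshold`. Zero rows when nothing qualifies.
#' @export
detect_segments <- function(series, threshold = 3, min_duration = 1,
                            gap_tolerance = 0) {
  stopifnot(threshold > 0, min_duration >= 1, gap_tolerance >= 0)
  values <- di_values(series)
  empty <- tibble::tibble(
    start_s = double(), end_s = double(), duration_s = double(),
    mean_di = double(), peak_di = double(), threshold = double()
  )
  if (length(values) == 0) return(empty)
  r <- rle(values > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based second of run start
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty)
  if (gap_tolerance > 0 && nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= gap_tolerance) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start >= min_duration, ]
  if (nrow(runs) == 0) return(empty)
  tibble::tibble(
    start_s = runs$start,
    end_s = runs$end,
    duration_s = runs$end - runs$start,
    mean_di = vapply(seq_len(nrow(runs)), function(i) {
      mean(values[(runs$start[i] + 1):runs$end[i]])
    }, 0),
    peak_di = vapply(seq_len(nrow(runs)), function(i) {
      max(values[(runs$start[i] + 1):runs$end[i]])
    }, 0),
    threshold = threshold
  )
}

#' Geolocate detected segments
#'
#' Annotates each segment with the GNSS fix nearest in time to its start
#' and end. Later segments receive later-or-equal fixes. A trace without
#' fixes returns the segments unannotated with a warning.
#'
#' @param segments Tibble from [detect_segments()].
#' @param trace The [logger_trace()] the series came from.
#' @return `segments` with added `start_lat`, `start_lon`, `start_fix_time`,
#'   `end_lat`, `end_lon`, `end_fix_time`.
#' @export
locate_segments <- function(segments, trace) {
  g <- trace$gnss
  if (nrow(g) == 0) {
    warning("trace has no GNSS fixes; segments returned unannotated",
            call. = FALSE)
    return(segments)
  }
  nearest <- function(t) {
    vapply(t, function(ti) which.min(abs(g$time - ti)), 0L)
  }
  si <- nearest(segments$start_s)
  ei <- nearest(segments$end_s)
  segments$start_fix_time <- g$time[si]
  segments$start_lat <- g$lat[si]
  segments$start_lon <- g$lon[si]
  segments$end_fix_time <- g$time[ei]
  segments$end_lat <- g$lat[ei]
  segments$end_lon <- g$lon[ei]
  segments
}

#' Export segment endpoints as GPX waypoints
#'
#' @param segments Geolocated segments from [locate_segments()].
#' @param path Output GPX path.
#' @return `path`, invisibly.
#' @export
export_segments_gpx <- function(segments, path) {
  if (!all(c("start_lat", "end_lat") %in% names(segments))) {
    stop("segments carry no coordinates; run locate_segments() first",
         call. = FALSE)
  }
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "roadvib",
    xmlns = "http://www.topografix.com/GPX/1/1"
  )
  for (i in seq_len(nrow(segments))) {
    for (side in c("start", "end")) {
      pt <- xml2::xml_add_child(
        doc, "wpt",
        lat = fmt_num(segments[[paste0(side, "_lat")]][i]),
        lon = fmt_num(segments[[paste0(side, "_lon")]][i])
      )
      xml2::xml_add_child(pt, "name",
                          sprintf("segment %d %s (t=%gs)", i, side,
                                  segments[[paste0(side, "_s")]][i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a delivery report to JSON
#'
#' @param report A `delivery_report`, optionally with a `segments` tibble
#'   attached.
#' @param path Output JSON path.
#' @param provenance Optional named list (seed, config) embedded verbatim.
#' @return `path`, invisibly.
#' @export
write_delivery_report <- function(report, path, provenance = NULL) {
  out <- list(
    duration_s = report$duration_s,
    overall_dbar = report$overall_dbar,
    distribution = report$distribution,
    quality = report$quality
  )
  if (!is.null(report$segments)) out$segments <- report$segments
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
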