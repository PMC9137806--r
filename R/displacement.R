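# The Displacement Index pipeline. D is the Euclidean distance between two
# consecutive tri-axial acceleration readings; D_i averages the f distances
# of one second; the trial mean Dbar averages the per-second D_i over a
# whole recording. All three are unit-covariant and invariant to a constant
# offset (gravity), so no gravity compensation is needed upstream.

#' Distance between two tri-axial acceleration readings
#'
#' Euclidean (vector-length) distance between two consecutive measurement
#' points in acceleration space,
#' \eqn{D = \sqrt{(x_n-x_m)^2 + (y_n-y_m)^2 + (z_n-z_m)^2}}.
#'
#' @param p_m,p_n Numeric vectors of length 3 (`ax`, `ay`, `az`), or
#'   one-row data frames with those columns.
#' @return Non-negative scalar distance, symmetric in its arguments.
#' @export
#' @examples
#' sample_distance(c(0, 0, 0), c(3, 4, 0)) # 5
sample_distance <- function(p_m, p_n) {
  p_m <- as_axis_triple(p_m)
  p_n <- as_axis_triple(p_n)
  if (!all(is.finite(p_m)) || !all(is.finite(p_n))) {
    stop("acceleration samples must be finite", call. = FALSE)
  }
  sqrt(sum((p_n - p_m)^2))
}

as_axis_triple <- function(p) {
  if (is.data.frame(p)) p <- c(p$ax, p$ay, p$az)
  p <- as.numeric(p)
  if (length(p) != 3) stop("a sample has exactly three axes", call. = FALSE)
  p
}

#' Per-second Displacement Index series of a trace
#'
#' Computes the distance between every pair of consecutive samples and
#' averages them within non-overlapping one-second windows of exactly `f`
#' distances each, aligned to the first distance. A trailing window with
#' fewer than `f` distances is dropped (a partial window would bias the
#' per-second mean), so a trace of `n` samples yields
#' `floor((n - 1) / f)` values.
#'
#' @param trace A [logger_trace()] with at least two samples.
#' @return A `displacement_series`: list with `values` (per-second
#'   \eqn{D_i}, 0-based second index), `f`, and the source `duration` in
#'   seconds.
#' @seealso [trial_mean()], [bin_distribution()], [classify_quality()]
#' @export
displacement_series <- function(trace) {
  validate_logger_trace(trace)
  s <- trace$samples
  if (nrow(s) < 2) {
    stop("insufficient data: need at least 2 samples", call. = FALSE)
  }
  d <- sqrt(diff(s$ax)^2 + diff(s$ay)^2 + diff(s$az)^2)
  f <- trace$f
  n_win <- floor(length(d) / f)
  values <- if (n_win > 0) {
    # columns of the matrix are the one-second windows
    colMeans(matrix(d[seq_len(n_win * f)], nrow = f))
  } else {
    double()
  }
  new_displacement_series(values, f = f, duration = trace_duration(trace))
}

new_displacement_series <- function(values, f, duration = length(values)) {
  stopifnot(all(values >= 0))
  structure(list(values = as.numeric(values), f = as.integer(f),
                 duration = duration),
            class = "displacement_series")
}

#' Build a displacement series from raw per-second values
#'
#' Convenience constructor for series that did not come from a trace (e.g.
#' values transcribed from a report).
#'
#' @param values Non-negative per-second Displacement Index values.
#' @param f Sampling frequency the values were derived at (Hz).
#' @return A `displacement_series`.
#' @export
as_displacement_series <- function(values, f = 50) {
  new_displacement_series(values, f = f)
}

di_values <- function(series) {
  if (inherits(series, "displacement_series")) series$values else as.numeric(series)
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("<displacement_series> %d s @ %d Hz, mean Di %.3f\n",
              length(x$values), x$f,
              if (length(x$values)) mean(x$values) else NA_real_))
  invisible(x)
}

#' Mean Displacement Index of a trial
#'
#' Arithmetic mean \eqn{\bar{D_x}} of the per-second index values over an
#' entire recording (the standardized trials use t = 60 s).
#'
#' @param series A [displacement_series] or numeric vector of per-second
#'   values; must be non-empty.
#' @return Scalar mean index.
#' @export
trial_mean <- function(series) {
  values <- di_values(series)
  if (length(values) == 0) {
    stop("insufficient data: empty displacement series", call. = FALSE)
  }
  mean(values)
}

#' Summarize one standardized road trial
#'
#' @param series A non-empty [displacement_series].
#' @param surface Road-surface label (`"A"` smooth asphalt, `"B"` rough
#'   asphalt, `"C"` cobblestone, `"D"` dirt road).
#' @param speed Trial speed in km/h.
#' @return One-row tibble with `surface`, `speed`, `dbar` (mean index),
#'   `min_di`, `max_di`, `seconds`.
#' @export
trial_summary <- function(series, surface, speed) {
  values <- di_values(series)
  tibble::tibble(
    surface = as.character(surface),
    speed = as.numeric(speed),
    dbar = trial_mean(values),
    min_di = min(values),
    max_di = max(values),
    seconds = length(values)
  )
}

#' Road-quality class of Displacement Index values
#'
#' Classifies per-second vibration intensity into road-condition classes:
#' `good` for \eqn{D_i \le 1} (few vibrations), `moderate` for
#' \eqn{1 < D_i < 1.5} (interrupted surfaces), `bad` for
#' \eqn{D_i \ge 1.5} (markedly increased vibrations). The classes partition
#' \eqn{[0, \infty)}; the upper boundary is assigned to `bad` so that
#' "at least 1.5" reads literally.
#'
#' @param di Numeric vector of non-negative index values.
#' @return Factor with levels `good`, `moderate`, `bad`.
#' @export
#' @examples
#' classify_quality(c(0.4, 1, 1.2, 1.5, 3))
classify_quality <- function(di) {
  di <- as.numeric(di)
  if (any(!is.finite(di)) || any(di < 0)) {
    stop("Displacement Index values must be finite and non-negative",
         call. = FALSE)
  }
  out <- ifelse(di <= 1, "good", ifelse(di < 1.5, "moderate", "bad"))
  factor(out, levels = c("good", "moderate", "bad"))
}

default_bin_edges <- c(0, 1, 2, 3, 4, 5, Inf)

bin_labels <- function(edges) {
  k <- length(edges) - 1
  lab <- character(k)
  lab[1] <- paste0("<=", format_edge(edges[2]))
  if (k > 1) {
    for (i in 2:k) {
      lab[i] <- if (is.infinite(edges[i + 1])) {
        paste0(">", format_edge(edges[i]))
      } else {
        paste0(">", format_edge(edges[i]), "-", format_edge(edges[i + 1]))
      }
    }
  }
  lab
}

format_edge <- function(x) format(x, trim = TRUE, drop0trailing = TRUE)

#' Bin a displacement series into intensity classes
#'
#' Counts seconds per Displacement-Index bin. With the default edges
#' `c(0, 1, 2, 3, 4, 5, Inf)` the bins are `<=1`, `>1-2`, ..., `>5`: the
#' first interval is closed at its upper edge and all later intervals are
#' left-open, so every value lands in exactly one bin. Absolute time per bin
#' is the second count (each value covers one second).
#'
#' @param series A non-empty [displacement_series] or numeric vector.
#' @param edges Strictly increasing bin boundaries covering all values.
#' @return Tibble with `bin` (label), `lower`, `upper`, `count`, `freq_pct`
#'   (relative frequency, %), `abs_time_s` and `abs_time_min`; the edge
#'   vector is attached as attribute `edges`.
#' @export
bin_distribution <- function(series, edges = default_bin_edges) {
  values <- di_values(series)
  if (length(values) == 0) stop("empty displacement series", call. = FALSE)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  if (any(values < edges[1] | values > edges[length(edges)])) {
    stop("values outside the binning range", call. = FALSE)
  }
  counts <- as.integer(table(cut(values, breaks = edges,
                                 include.lowest = TRUE, right = TRUE)))
  out <- tibble::tibble(
    bin = bin_labels(edges),
    lower = head(edges, -1),
    upper = tail(edges, -1),
    count = counts,
    freq_pct = counts / length(values) * 100,
    abs_time_s = counts,
    abs_time_min = counts / 60
  )
  attr(out, "edges") <- edges
  out
}
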