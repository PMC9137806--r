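# Seeded generator for synthetic road traces. The noise model is iid
# Gaussian acceleration per axis around a constant gravity vector: the
# difference of two consecutive samples is then Gaussian with SD
# sigma * sqrt(2) per axis, its Euclidean norm follows a 3-d chi
# distribution, and E[D] = (4 / sqrt(pi)) * sigma. Inverting that mean is
# the whole calibration, so a target per-second index maps linearly to a
# per-axis noise scale.

#' Per-axis noise scale for a target Displacement Index
#'
#' Inverts the generator's noise model: with iid Gaussian samples of SD
#' \eqn{\sigma_a} per axis, the expected consecutive-sample distance is
#' \eqn{E[D] = 4\sigma_a/\sqrt{\pi}}, hence
#' \eqn{\sigma_a = \mathrm{target} \cdot \sqrt{\pi}/4}. Linear in the
#' target; 0 maps to 0.
#'
#' @param target_di Desired mean per-second Displacement Index (>= 0).
#' @return Per-axis Gaussian SD \eqn{\sigma_a}.
#' @export
calibrate_sigma <- function(target_di) {
  if (any(!is.finite(target_di)) || any(target_di < 0)) {
    stop("target Displacement Index must be finite and non-negative",
         call. = FALSE)
  }
  target_di * sqrt(pi) / 4
}

#' Vibration model of one road-surface x speed category
#'
#' @param surface Surface label (`"A"` smooth asphalt, `"B"` rough asphalt,
#'   `"C"` cobblestone, `"D"` dirt road).
#' @param speed Speed in km/h.
#' @param target_dbar Intended mean trial index \eqn{\bar{D_x}} of the
#'   category.
#' @param between_trial_sd SD of \eqn{\bar{D_x}} across repeated trials.
#' @param impulse_rate Short shock events per minute (potholes, impacts).
#' @param impulse_scale Impulse amplitude as a multiple of the base
#'   per-axis noise scale.
#' @return One-row tibble usable by [simulate_trial()].
#' @export
surface_model <- function(surface, speed, target_dbar, between_trial_sd,
                          impulse_rate = 0, impulse_scale = 5) {
  stopifnot(target_dbar >= 0, between_trial_sd >= 0, impulse_rate >= 0)
  tibble::tibble(
    surface = as.character(surface), speed = as.numeric(speed),
    target_dbar = target_dbar, between_trial_sd = between_trial_sd,
    impulse_rate = impulse_rate, impulse_scale = impulse_scale
  )
}

#' Standardized road-trial design
#'
#' The 12 observed road-surface x speed categories of the standardized
#' trials with 10 replicates each (n = 120): smooth asphalt at 30--150
#' km/h, rough asphalt at 30--120 km/h, cobblestone at 30 and 60 km/h, and
#' dirt road at 30 km/h. Intensity parameters (`target_dbar`,
#' `between_trial_sd`) are the published per-category mean and SD of the
#' trial index; impulse defaults reflect the surface character: none on
#' smooth asphalt and cobblestone (continuous vibration), occasional on
#' rough asphalt, frequent irregular impacts on dirt road.
#'
#' @return Tibble of 12 [surface_model()] rows plus a `replicates` column.
#' @export
default_trial_design <- function() {
  d <- tibble::tribble(
    ~surface, ~speed, ~target_dbar, ~between_trial_sd,
    "A", 30,  0.36, 0.05,
    "A", 60,  0.46, 0.02,
    "A", 90,  0.58, 0.04,
    "A", 120, 0.74, 0.05,
    "A", 150, 0.95, 0.10,
    "B", 30,  0.97, 0.26,
    "B", 60,  0.80, 0.07,
    "B", 90,  0.78, 0.05,
    "B", 120, 0.86, 0.06,
    "C", 30,  3.60, 0.18,
    "C", 60,  4.44, 0.09,
    "D", 30,  2.14, 0.21
  )
  d$impulse_rate <- unname(c(A = 0, B = 2, C = 0, D = 6)[d$surface])
  d$impulse_scale <- 5
  d$replicates <- 10L
  d
}

# Raw sample matrix for one homogeneous stretch of road; consumes RNG in a
# fixed order (intensity draw, base noise, impulse count/placement/noise).
simulate_segment_samples <- function(model, duration, f,
                                     gravity = c(0, 0, 1)) {
  intensity <- max(0, rnorm(1, model$target_dbar, model$between_trial_sd))
  sigma <- calibrate_sigma(intensity)
  n <- as.integer(round(duration * f))
  acc <- matrix(rnorm(3L * n, mean = 0, sd = sigma), ncol = 3)
  n_impulse <- rpois(1, model$impulse_rate / 60 * duration)
  if (n_impulse > 0 && sigma > 0) {
    starts <- runif(n_impulse, 0, duration)
    lengths <- runif(n_impulse, 0.04, 0.2) # short bursts, <= 0.2 s
    for (j in seq_len(n_impulse)) {
      idx <- seq.int(floor(starts[j] * f) + 1,
                     min(n, ceiling((starts[j] + lengths[j]) * f)))
      acc[idx, ] <- acc[idx, ] +
        rnorm(3L * length(idx), mean = 0, sd = model$impulse_scale * sigma)
    }
  }
  sweep(acc, 2, gravity, `+`)
}

#' Simulate one standardized road trial
#'
#' Generates a trace following the standardized protocol (default 60 s at
#' 50 Hz): the trial's intensity is drawn as
#' Normal(`target_dbar`, `between_trial_sd`) truncated at 0, converted to a
#' per-axis noise scale with [calibrate_sigma()], and iid Gaussian samples
#' are placed around a constant gravity vector; Poisson-placed impulse
#' bursts (\eqn{\le} 0.2 s) add extra amplitude. The same seed always
#' yields the identical trace. Surface and speed are recorded as
#' annotations at t = 0.
#'
#' @param model A [surface_model()] row.
#' @param duration Trial length in seconds.
#' @param f Sampling frequency in Hz.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @param gravity Constant acceleration offset vector (g units); has no
#'   effect on any downstream index value.
#' @return A [logger_trace()].
#' @export
simulate_trial <- function(model, duration = 60, f = 50, seed = NULL,
                           gravity = c(0, 0, 1)) {
  stopifnot(nrow(model) == 1, duration > 0, f > 0)
  acc <- maybe_with_seed(seed, simulate_segment_samples(model, duration, f, gravity))
  logger_trace(
    f = f,
    samples = acc,
    annotations = tibble::tibble(
      time = c(0, 0),
      kind = c("road_surface", "speed"),
      value = c(model$surface, format(model$speed))
    ),
    meta = list(device = "roadvib-synthetic",
                date = "1970-01-01T00:00:00Z")
  )
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, force(code))
}

#' Simulate a full trial design
#'
#' Runs [simulate_trial()] for every design row and replicate. The RNG is a
#' single base seed split by trial counter: trial `i` (row-major over
#' design rows, then replicates) uses `seed + i - 1`, so any single trial
#' can be regenerated independently.
#'
#' @param design Tibble of [surface_model()] rows with a `replicates`
#'   column; defaults to [default_trial_design()].
#' @param duration,f Protocol parameters passed to [simulate_trial()].
#' @param seed Integer base seed.
#' @return List of `logger_trace` objects; each carries `surface`, `speed`,
#'   `replicate` and `seed` in its `meta`.
#' @export
simulate_design <- function(design = default_trial_design(), duration = 60,
                            f = 50, seed = 1) {
  traces <- vector("list", sum(design$replicates))
  counter <- 0L
  for (r in seq_len(nrow(design))) {
    model <- design[r, ]
    for (rep in seq_len(model$replicates)) {
      counter <- counter + 1L
      tr <- simulate_trial(model, duration = duration, f = f,
                           seed = seed + counter - 1L)
      tr$meta$surface <- model$surface
      tr$meta$speed <- model$speed
      tr$meta$replicate <- rep
      tr$meta$seed <- seed + counter - 1L
      traces[[counter]] <- tr
    }
  }
  traces
}

#' Trial results for a set of traces
#'
#' Computes the per-trial summary ([trial_summary()]) for every trace,
#' reading surface and speed from trace annotations (or `meta` for
#' simulated traces).
#'
#' @param traces List of `logger_trace` objects.
#' @return Tibble with one row per trace: `surface`, `speed`, `dbar`,
#'   `min_di`, `max_di`, `seconds`.
#' @export
summarize_trials <- function(traces) {
  dplyr::bind_rows(lapply(traces, function(tr) {
    lab <- trace_category(tr)
    trial_summary(displacement_series(tr), lab$surface, lab$speed)
  }))
}

trace_category <- function(trace) {
  surface <- trace$meta$surface
  speed <- trace$meta$speed
  a <- trace$annotations
  if (is.null(surface)) {
    s <- a$value[a$kind == "road_surface"]
    if (length(s) > 0) surface <- s[1]
  }
  if (is.null(speed)) {
    v <- a$value[a$kind == "speed"]
    if (length(v) > 0) speed <- as.numeric(v[1])
  }
  if (is.null(surface) || is.null(speed)) {
    stop("trace has no road_surface/speed annotation", call. = FALSE)
  }
  list(surface = surface, speed = as.numeric(speed))
}

#' Build a delivery route plan
#'
#' A route plan is an ordered set of contiguous road segments, each with a
#' vibration model, a duration, and straight-line GNSS endpoints.
#'
#' @param segments Data frame with the [surface_model()] columns plus
#'   `duration_s`, `start_lat`, `start_lon`, `end_lat`, `end_lon`.
#' @return Tibble of class `route_plan` with a `t_start` column (cumulative
#'   segment start time, s).
#' @export
route_plan <- function(segments) {
  segments <- tibble::as_tibble(segments)
  need <- c("surface", "speed", "target_dbar", "between_trial_sd",
            "duration_s", "start_lat", "start_lon", "end_lat", "end_lon")
  missing <- setdiff(need, names(segments))
  if (length(missing) > 0) {
    stop("route plan is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments) == 0) stop("route plan has no segments", call. = FALSE)
  if (any(segments$duration_s <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (!"impulse_rate" %in% names(segments)) segments$impulse_rate <- 0
  if (!"impulse_scale" %in% names(segments)) segments$impulse_scale <- 5
  segments$t_start <- cumsum(c(0, head(segments$duration_s, -1)))
  class(segments) <- c("route_plan", class(segments))
  segments
}

#' Read a route plan from a YAML file
#'
#' The file holds a top-level `segments:` list; each entry gives `surface`,
#' `speed`, `target_dbar`, `between_trial_sd`, `duration_s` and the
#' `start`/`end` coordinates as `[lat, lon]` pairs (optionally
#' `impulse_rate`, `impulse_scale`).
#'
#' @param path YAML file path.
#' @return A [route_plan()].
#' @export
read_route_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$segments)) stop("route file has no 'segments' list", call. = FALSE)
  rows <- lapply(cfg$segments, function(s) {
    tibble::tibble(
      surface = s$surface, speed = s$speed,
      target_dbar = s$target_dbar, between_trial_sd = s$between_trial_sd,
      impulse_rate = s$impulse_rate %||% 0,
      impulse_scale = s$impulse_scale %||% 5,
      duration_s = s$duration_s,
      start_lat = s$start[[1]], start_lon = s$start[[2]],
      end_lat = s$end[[1]], end_lon = s$end[[2]]
    )
  })
  route_plan(dplyr::bind_rows(rows))
}

#' Simulate a multi-segment field delivery
#'
#' Concatenates per-segment simulations (each segment drawn like a trial of
#' its own [surface_model()]), interpolates a 1 Hz GNSS track linearly
#' between segment endpoints, and annotates segment boundaries with surface
#' and speed. Segment `j` uses seed `seed + j - 1`, so a single-segment
#' delivery reproduces [simulate_trial()] with the same seed sample for
#' sample.
#'
#' @param plan A [route_plan()].
#' @param f Sampling frequency in Hz.
#' @param seed Integer base seed; `NULL` uses the current RNG state.
#' @param gravity Constant acceleration offset vector.
#' @return A [logger_trace()] with GNSS fixes at 1 Hz.
#' @export
simulate_delivery <- function(plan, f = 50, seed = NULL,
                              gravity = c(0, 0, 1)) {
  if (!inherits(plan, "route_plan")) plan <- route_plan(plan)
  acc <- vector("list", nrow(plan))
  for (j in seq_len(nrow(plan))) {
    acc[[j]] <- maybe_with_seed(
      if (is.null(seed)) NULL else seed + j - 1L,
      simulate_segment_samples(plan[j, ], plan$duration_s[j], f, gravity)
    )
  }
  acc <- do.call(rbind, acc)
  total <- sum(plan$duration_s)

  # piecewise-linear position over segment endpoints, sampled at 1 Hz
  t_knots <- c(rbind(plan$t_start, plan$t_start + plan$duration_s))
  lat_knots <- c(rbind(plan$start_lat, plan$end_lat))
  lon_knots <- c(rbind(plan$start_lon, plan$end_lon))
  fix_times <- seq(0, total, by = 1)
  gnss <- tibble::tibble(
    time = fix_times,
    lat = approx(t_knots, lat_knots, xout = fix_times, ties = "ordered")$y,
    lon = approx(t_knots, lon_knots, xout = fix_times, ties = "ordered")$y,
    elevation = NA_real_
  )

  annotations <- tibble::tibble(
    time = rep(plan$t_start, each = 2),
    kind = rep(c("road_surface", "speed"), nrow(plan)),
    value = as.vector(rbind(plan$surface, format(plan$speed)))
  )

  logger_trace(
    f = f, samples = acc, gnss = gnss, annotations = annotations,
    meta = list(device = "roadvib-synthetic",
                date = "1970-01-01T00:00:00Z")
  )
}
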