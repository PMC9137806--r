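# Shared fixtures and independent oracles. The oracles deliberately use
# naive loops (no vectorization shared with the implementation).

# Random trace whose numeric fields are exactly representable at the log
# format's serialized precision, so round trips compare exactly.
random_trace <- function(n_samples = 120, f = 10, seed = 1,
                         n_aux = 3, n_gnss = 4, n_ann = 3) {
  withr::with_seed(seed, {
    dur <- n_samples / f
    aux <- if (n_aux > 0) {
      tibble::tibble(
        time = round(sort(runif(n_aux, 0, dur)), 2),
        channel = sample(c("temperature", "pressure", "humidity"), n_aux,
                         replace = TRUE),
        value = signif(runif(n_aux, 0, 40), 6)
      )
    }
    gnss <- if (n_gnss > 0) {
      tibble::tibble(
        time = round(sort(runif(n_gnss, 0, dur)), 2),
        lat = round(runif(n_gnss, 50, 54), 6),
        lon = round(runif(n_gnss, 8, 11), 6),
        elevation = c(round(runif(max(0, n_gnss - 1), 0, 300), 2), NA)
      )
    }
    annotations <- if (n_ann > 0) {
      tibble::tibble(
        time = round(sort(runif(n_ann, 0, dur)), 2),
        kind = c("road_surface", "speed", "event")[seq_len(n_ann)],
        value = c("B", "60", "pothole")[seq_len(n_ann)]
      )
    }
    logger_trace(
      f = f,
      samples = tibble::tibble(
        index = seq_len(n_samples) - 1L,
        ax = signif(rnorm(n_samples), 6),
        ay = signif(rnorm(n_samples), 6),
        az = signif(rnorm(n_samples), 6)
      ),
      aux = aux, gnss = gnss, annotations = annotations,
      meta = list(date = "2021-06-01T10:00:00Z", device = "logger-01")
    )
  })
}

# Naive double-loop Displacement Index: per-sample distances one by one,
# then explicit per-second windows.
brute_force_di <- function(trace) {
  s <- trace$samples
  f <- trace$f
  n <- nrow(s)
  d <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    d[k] <- sqrt((s$ax[k + 1] - s$ax[k])^2 +
                 (s$ay[k + 1] - s$ay[k])^2 +
                 (s$az[k + 1] - s$az[k])^2)
  }
  n_win <- floor(length(d) / f)
  out <- numeric(n_win)
  for (w in seq_len(n_win)) {
    acc <- 0
    for (k in seq_len(f)) acc <- acc + d[(w - 1) * f + k]
    out[w] <- acc / f
  }
  out
}

# Linear-scan run-length detector over a logical vector (1 value = 1 s).
brute_force_runs <- function(above, min_duration) {
  runs <- list()
  start <- NA
  for (i in seq_along(above)) {
    if (above[i] && is.na(start)) start <- i - 1
    if (!above[i] && !is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(above))
  runs <- Filter(function(r) r[2] - r[1] >= min_duration, runs)
  if (length(runs) == 0) {
    return(data.frame(start_s = double(), end_s = double()))
  }
  do.call(rbind.data.frame, lapply(runs, function(r) {
    data.frame(start_s = r[1], end_s = r[2])
  }))
}

# Trials table whose 12 cell means AND sample SDs equal the study's
# per-category parameters exactly: dbar = mean + sd * u with u a fixed
# zero-mean, unit-sample-SD pattern of length 10.
table2_mean_trials_with_sd <- function() {
  design <- default_trial_design()
  u <- c(-1.5, -1, -0.5, -0.25, 0, 0, 0.25, 0.5, 1, 1.5)
  u <- (u - mean(u)) / sd(u)
  dplyr::bind_rows(lapply(seq_len(nrow(design)), function(r) {
    tibble::tibble(
      surface = design$surface[r],
      speed = design$speed[r],
      dbar = design$target_dbar[r] + design$between_trial_sd[r] * u,
      min_di = pmax(0, design$target_dbar[r] - 1),
      max_di = design$target_dbar[r] + 1,
      seconds = 60
    )
  }))
}

# Trials table whose 12 cell means equal the published per-category means
# exactly (10 replicates each, zero-sum perturbations keep the mean exact
# and the residual variance positive).
table2_mean_trials <- function() {
  design <- default_trial_design()
  perturb <- c(-0.02, 0.02, -0.01, 0.01, 0, 0, -0.03, 0.03, -0.015, 0.015)
  dplyr::bind_rows(lapply(seq_len(nrow(design)), function(r) {
    tibble::tibble(
      surface = design$surface[r],
      speed = design$speed[r],
      dbar = design$target_dbar[r] + perturb,
      min_di = design$target_dbar[r] - 0.5,
      max_di = design$target_dbar[r] + 0.5,
      seconds = 60
    )
  }))
}
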