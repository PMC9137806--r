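# Study-level statistics over standardized trials. The design is
# incomplete (not every surface was driven at every speed): the linear
# model is fit on observed cells only, and R's aliasing of inestimable
# interaction terms yields the design-determined degrees of freedom
# (interaction df = observed cells - 1 - df_speed - df_surface).

cell_label <- function(surface, speed) {
  paste0(surface, "-", format(speed, trim = TRUE))
}

check_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("surface", "speed", "dbar")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials
}

#' Per-category summary of standardized road trials
#'
#' For each road-surface x speed category: mean and sample SD (n - 1
#' denominator) of the per-trial mean index \eqn{\bar{D_x}}, the
#' coefficient of variation (SD/mean x 100), and the minimum and maximum
#' per-second \eqn{D_i} pooled over all the category's trials.
#'
#' @param trials Tibble of trial results as returned by [trial_summary()] /
#'   [summarize_trials()] (columns `surface`, `speed`, `dbar`, `min_di`,
#'   `max_di`).
#' @return Tibble with one row per category: `surface`, `speed`,
#'   `n_trials`, `mean_dbar`, `sd_dbar`, `cv_pct`, `min_di`, `max_di`, and
#'   a `single_trial` flag (SD reported as 0 when only one trial exists).
#' @export
category_summary <- function(trials) {
  trials <- check_trials(trials)
  out <- trials |>
    dplyr::group_by(.data$surface, .data$speed) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_dbar = mean(.data$dbar),
      sd_dbar = if (dplyr::n() > 1) sd(.data$dbar) else 0,
      min_di = min(.data$min_di),
      max_di = max(.data$max_di),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_pct = ifelse(.data$mean_dbar > 0,
                      .data$sd_dbar / .data$mean_dbar * 100, 0),
      single_trial = .data$n_trials == 1
    ) |>
    dplyr::arrange(.data$surface, .data$speed) |>
    dplyr::select("surface", "speed", "n_trials", "mean_dbar", "sd_dbar",
                  "cv_pct", "min_di", "max_di", "single_trial")
  if (any(out$single_trial)) {
    warning("categories with a single trial report SD = 0", call. = FALSE)
  }
  out
}

#' Two-way ANOVA of trial means on speed and road surface
#'
#' Sequential (Type I) sum-of-squares decomposition of the per-trial mean
#' index \eqn{\bar{D_x}} on speed, road surface, and their interaction,
#' both treated as factors. Cells absent from the design are never imputed:
#' the model is fit on observed cells only and inestimable interaction
#' contrasts are dropped, so for the standardized 12-cell, 10-replicate
#' design the interaction has 4 df and the residual 108 df.
#'
#' @param trials Trial-result tibble (`surface`, `speed`, `dbar`); at least
#'   two categories with at least two trials each.
#' @return Tibble with `term` (`speed`, `surface`, `speed:surface`,
#'   `residuals`), `df`, `sumsq`, `meansq`, `statistic`, `p.value`
#'   (`NA` where an F ratio is undefined).
#' @export
two_way_anova <- function(trials) {
  trials <- check_trials(trials)
  cells <- paste(trials$surface, trials$speed)
  if (length(unique(cells)) < 2) {
    stop("need at least two surface x speed categories", call. = FALSE)
  }
  if (min(table(cells)) < 2) {
    stop("need at least two trials per category", call. = FALSE)
  }
  d <- data.frame(
    dbar = trials$dbar,
    speed_f = factor(trials$speed),
    surface_f = factor(trials$surface)
  )
  # a factor observed at a single level contributes nothing (0 df)
  rhs <- c(
    if (nlevels(d$speed_f) > 1) "speed_f",
    if (nlevels(d$surface_f) > 1) "surface_f"
  )
  if (length(rhs) == 2) rhs <- c(rhs, "speed_f:surface_f")
  fit <- lm(stats::reformulate(rhs, response = "dbar"), data = d)
  a <- anova(fit)
  pick <- function(row, col) {
    if (row %in% rownames(a)) a[row, col] else if (col == "Df") 0L else 0
  }
  rows <- c(speed = "speed_f", surface = "surface_f",
            `speed:surface` = "speed_f:surface_f", residuals = "Residuals")
  out <- tibble::tibble(
    term = names(rows),
    df = unname(vapply(rows, pick, 0L, col = "Df")),
    sumsq = unname(vapply(rows, pick, 0, col = "Sum Sq")),
    meansq = unname(vapply(rows, pick, 0, col = "Mean Sq")),
    statistic = unname(vapply(rows, pick, 0, col = "F value")),
    p.value = unname(vapply(rows, pick, 0, col = "Pr(>F)"))
  )
  # numerically zero SS (constant data) leaves the F ratio undefined
  eps <- 1e-12 * (1 + sum(trials$dbar^2))
  out$sumsq[out$sumsq < eps] <- 0
  resid_ms <- out$meansq[out$term == "residuals"]
  zero <- out$df == 0 | out$term == "residuals" | !is.finite(out$statistic) |
    out$sumsq == 0 | resid_ms < eps
  out$statistic[zero] <- NA_real_
  out$p.value[zero] <- NA_real_
  out$meansq[out$df == 0] <- NA_real_
  out
}

#' Tukey HSD comparisons of category means
#'
#' All pairwise comparisons among the observed surface x speed cell means,
#' using the studentized-range distribution with the pooled residual mean
#' square of the cell-means model (Tukey--Kramer standard error for
#' unequal cell sizes). The whole set of cell pairs forms one family for
#' the adjusted p-values and family-wise confidence intervals. Cells are
#' ordered by surface then speed, and `mean_diff` is always
#' `mean(group_i) - mean(group_ii)` with `group_i` the earlier cell.
#'
#' @param trials Trial-result tibble (`surface`, `speed`, `dbar`).
#' @param conf.level Family-wise confidence level for the intervals.
#' @return Tibble with `group_i`, `group_ii` (cell labels like `"A-30"`),
#'   the factor columns `surface_i`, `speed_i`, `surface_ii`, `speed_ii`,
#'   `mean_diff`, `p_adj`, `ci_lower`, `ci_upper`, and a `signif` star
#'   column (`*` p < 0.05, `***` p < 0.001). Attributes `n_means`, `df`
#'   and `mse` carry the family size and pooled error.
#' @export
tukey_hsd <- function(trials, conf.level = 0.95) {
  trials <- check_trials(trials)
  d <- tibble::tibble(
    surface = trials$surface, speed = trials$speed, dbar = trials$dbar
  ) |>
    dplyr::arrange(.data$surface, .data$speed)
  cells <- d |>
    dplyr::group_by(.data$surface, .data$speed) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$dbar),
                     ss = sum((.data$dbar - mean(.data$dbar))^2),
                     .groups = "drop") |>
    dplyr::arrange(.data$surface, .data$speed)
  k <- nrow(cells)
  if (k < 2) stop("need at least two categories", call. = FALSE)
  df_resid <- sum(cells$n) - k
  if (df_resid < 1) stop("Tukey HSD needs residual df >= 1", call. = FALSE)
  mse <- sum(cells$ss) / df_resid
  degenerate <- mse <= 0
  if (degenerate) {
    warning("zero residual variance: adjusted p-values are degenerate",
            call. = FALSE)
  }

  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  diff <- cells$m[i] - cells$m[j]
  se <- sqrt(mse / 2 * (1 / cells$n[i] + 1 / cells$n[j]))
  if (degenerate) {
    p <- ifelse(diff == 0, 1, 0)
    hw <- 0
  } else {
    p <- ptukey(abs(diff) / se, nmeans = k, df = df_resid, lower.tail = FALSE)
    hw <- qtukey(conf.level, nmeans = k, df = df_resid) * se
  }
  out <- tibble::tibble(
    group_i = cell_label(cells$surface[i], cells$speed[i]),
    group_ii = cell_label(cells$surface[j], cells$speed[j]),
    surface_i = cells$surface[i], speed_i = cells$speed[i],
    surface_ii = cells$surface[j], speed_ii = cells$speed[j],
    mean_diff = diff,
    p_adj = p,
    ci_lower = diff - hw,
    ci_upper = diff + hw,
    signif = ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
  )
  attr(out, "n_means") <- k
  attr(out, "df") <- df_resid
  attr(out, "mse") <- mse
  out
}

#' Single-factor view of Tukey comparisons
#'
#' Restricts [tukey_hsd()] output to pairs that differ in exactly one of
#' road surface or speed — the comparisons that answer "same road, other
#' speed" and "same speed, other road" — grouped with the speed-varying
#' block first.
#'
#' @param comparisons Tibble from [tukey_hsd()].
#' @return Filtered tibble with an extra `varying` column (`"speed"` or
#'   `"surface"`).
#' @export
single_factor_view <- function(comparisons) {
  same_surface <- comparisons$surface_i == comparisons$surface_ii
  same_speed <- comparisons$speed_i == comparisons$speed_ii
  out <- comparisons |>
    dplyr::mutate(varying = dplyr::case_when(
      same_surface & !same_speed ~ "speed",
      same_speed & !same_surface ~ "surface",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$varying)) |>
    dplyr::arrange(dplyr::desc(.data$varying == "speed"))
  out
}
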