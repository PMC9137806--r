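test_that("category summaries compute sample SD, CV and pooled extremes", {
  trials <- tibble::tibble(
    surface = c("A", "A", "A", "C", "C"),
    speed = c(30, 30, 30, 60, 60),
    dbar = c(1, 1, 1, 1, 3),
    min_di = c(0.5, 0.4, 0.6, 0.9, 1.1),
    max_di = c(1.4, 1.6, 1.5, 3.9, 4.1),
    seconds = 60
  )
  cs <- category_summary(trials)
  a30 <- cs[cs$surface == "A", ]
  expect_equal(a30$mean_dbar, 1)
  expect_equal(a30$sd_dbar, 0)
  expect_equal(a30$cv_pct, 0)
  expect_equal(a30$min_di, 0.4)
  expect_equal(a30$max_di, 1.6)
  c60 <- cs[cs$surface == "C", ]
  expect_equal(c60$mean_dbar, 2)
  expect_equal(c60$sd_dbar, sqrt(2))
  expect_equal(c60$cv_pct, sqrt(2) / 2 * 100, tolerance = 1e-9)

  expect_warning(
    category_summary(tibble::tibble(surface = "D", speed = 30, dbar = 2,
                                    min_di = 1, max_di = 3, seconds = 60)),
    "single trial"
  )
})

test_that("rough asphalt at 30 km/h has the highest CV under the study parameters", {
  cs <- category_summary(table2_mean_trials_with_sd())
  top <- cs[which.max(cs$cv_pct), ]
  expect_equal(top$surface, "B")
  expect_equal(top$speed, 30)
  expect_equal(top$cv_pct, 26.8, tolerance = 0.01)
})

test_that("sequential two-way ANOVA matches a closed-form balanced oracle", {
  # balanced 2x2 with replicates: textbook projection formulas
  d <- tibble::tibble(
    surface = rep(c("A", "B"), each = 4),
    speed = rep(c(30, 60), times = 4),
    dbar = c(1.0, 2.0, 1.2, 2.1, 3.0, 4.5, 3.1, 4.4),
    min_di = 0, max_di = 9, seconds = 60
  )
  got <- two_way_anova(d)

  grand <- mean(d$dbar)
  cell <- tapply(d$dbar, list(d$speed, d$surface), mean)
  m_speed <- tapply(d$dbar, d$speed, mean)
  m_surf <- tapply(d$dbar, d$surface, mean)
  ss_speed <- 4 * sum((m_speed - grand)^2)
  ss_surf <- 4 * sum((m_surf - grand)^2)
  ss_cells <- 2 * sum((cell - grand)^2)
  ss_int <- ss_cells - ss_speed - ss_surf
  ss_res <- sum((d$dbar - cell[cbind(as.character(d$speed), d$surface)])^2)

  expect_equal(got$sumsq, c(ss_speed, ss_surf, ss_int, ss_res),
               tolerance = 1e-9)
  expect_equal(got$df, c(1, 1, 1, 4))
  expect_equal(sum(got$sumsq), sum((d$dbar - grand)^2), tolerance = 1e-9)
})

test_that("the incomplete 12-cell design yields the design-determined df", {
  withr::with_seed(2, {
    trials <- table2_mean_trials()
    trials$dbar <- trials$dbar + rnorm(nrow(trials), 0, 0.01)
  })
  a <- two_way_anova(trials)
  expect_equal(a$df[a$term == "speed"], 4L)
  expect_equal(a$df[a$term == "surface"], 3L)
  expect_equal(a$df[a$term == "speed:surface"], 4L)
  expect_equal(a$df[a$term == "residuals"], 108L)
  expect_equal(sum(a$df), 120 - 1)
  expect_equal(sum(a$sumsq),
               sum((trials$dbar - mean(trials$dbar))^2), tolerance = 1e-9)
})

test_that("constant data gives zero effect SS and undefined F", {
  d <- tibble::tibble(
    surface = rep(c("A", "B"), each = 4),
    speed = rep(c(30, 60), times = 4),
    dbar = 2, min_di = 2, max_di = 2, seconds = 60
  )
  a <- suppressWarnings(two_way_anova(d)) # perfect-fit warning from anova
  expect_equal(a$sumsq, rep(0, 4), tolerance = 1e-12)
  expect_true(all(is.na(a$p.value[1:3])))
  expect_error(two_way_anova(d[c(1, 3), ]), "two")
  # one factor at a single level: its term (and the interaction) has 0 df
  one_speed <- tibble::tibble(
    surface = rep(c("A", "C"), each = 3), speed = 30,
    dbar = c(0.3, 0.4, 0.35, 3.5, 3.7, 3.6), min_di = 0, max_di = 8,
    seconds = 60
  )
  a1 <- two_way_anova(one_speed)
  expect_equal(a1$df, c(0L, 1L, 0L, 4L))
  expect_true(a1$p.value[a1$term == "surface"] < 0.001)
})

test_that("Tukey HSD agrees with stats::TukeyHSD and the two-group t-test", {
  withr::with_seed(31, {
    trials <- tibble::tibble(
      surface = rep(c("A", "B", "C"), each = 6),
      speed = 30,
      dbar = rnorm(18, rep(c(1, 2, 4), each = 6), 0.3),
      min_di = 0, max_di = 9, seconds = 60
    )
  })
  got <- tukey_hsd(trials)
  ref <- stats::TukeyHSD(stats::aov(dbar ~ cell, data = data.frame(
    dbar = trials$dbar, cell = factor(paste0(trials$surface, "-30"))
  )))$cell
  # reference reports later-minus-earlier; ours is group I minus group II
  expect_equal(got$mean_diff, -unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(got$p_adj, unname(ref[, "p adj"]), tolerance = 1e-7)
  expect_equal(got$ci_lower, -unname(ref[, "upr"]), tolerance = 1e-9)
  expect_equal(got$ci_upper, -unname(ref[, "lwr"]), tolerance = 1e-9)

  # k = 2: studentized-range p equals the pooled two-sample t-test p
  two <- trials[trials$surface != "C", ]
  got2 <- tukey_hsd(two)
  tt <- stats::t.test(dbar ~ surface, data = two, var.equal = TRUE)
  expect_equal(got2$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("degenerate and identical-group cases behave as declared", {
  same <- tibble::tibble(
    surface = rep(c("A", "B"), each = 5), speed = 30,
    dbar = rep(c(1, 1), each = 5) + rep(c(-0.1, 0.1, 0, -0.2, 0.2), 2),
    min_di = 0, max_di = 2, seconds = 60
  )
  got <- tukey_hsd(same)
  expect_equal(got$mean_diff, 0, tolerance = 1e-12)
  expect_equal(got$p_adj, 1, tolerance = 1e-9)

  flat <- tibble::tibble(
    surface = rep(c("A", "B"), each = 3), speed = 30,
    dbar = rep(c(1, 2), each = 3), min_di = 0, max_di = 3, seconds = 60
  )
  expect_warning(dg <- tukey_hsd(flat), "zero residual variance")
  expect_equal(dg$p_adj, 0)
})

test_that("single-factor view keeps pairs differing in exactly one factor", {
  withr::with_seed(17, {
    trials <- table2_mean_trials()
    trials$dbar <- trials$dbar + rnorm(nrow(trials), 0, 0.01)
  })
  comps <- tukey_hsd(trials)
  expect_equal(nrow(comps), choose(12, 2))
  view <- single_factor_view(comps)

  # enumeration oracle over the 12 observed cells
  cells <- unique(trials[c("surface", "speed")])
  pairs <- utils::combn(nrow(cells), 2)
  one_factor <- apply(pairs, 2, function(p) {
    (cells$surface[p[1]] == cells$surface[p[2]]) !=
      (cells$speed[p[1]] == cells$speed[p[2]])
  })
  n_speed <- sum(apply(pairs, 2, function(p) {
    cells$surface[p[1]] == cells$surface[p[2]] &&
      cells$speed[p[1]] != cells$speed[p[2]]
  }))
  expect_equal(nrow(view), sum(one_factor))
  expect_equal(sum(view$varying == "speed"), n_speed)
  expect_equal(sum(view$varying == "speed"), 17)
  expect_equal(sum(view$varying == "surface"), 11)

  expect_false(any(view$group_i == "A-30" & view$group_ii == "B-60"))
  expect_true(any(view$group_i == "A-30" & view$group_ii == "A-60" &
                    view$varying == "speed"))
  # speed block listed before the surface block
  expect_equal(unique(view$varying), c("speed", "surface"))
})
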