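test_that("the dose window keeps exactly the GR [0, 1] points", {
  prof <- tibble::tibble(gr = c(1.0, 0.8, 0.4, -0.2, -0.6),
                         fv = c(1, 0.95, 0.8, 0.5, 0.3),
                         dose = 10^(-8:-4))
  win <- select_dose_window(prof)
  expect_equal(win$gr, c(1.0, 0.8, 0.4))

  full <- tibble::tibble(gr = c(0.9, 0.5, 0.1), fv = c(1, 0.8, 0.6))
  expect_equal(nrow(select_dose_window(full)), 3)
})

test_that("unusable profiles are refused with informative classes", {
  flat <- tibble::tibble(gr = c(0.96, 0.95, 0.97), fv = c(0.99, 0.98, 0.99))
  expect_error(select_dose_window(flat), class = "druggrade_error_non_functional")
  single <- tibble::tibble(gr = c(1.0, -0.5), fv = c(1, 0.4))
  expect_error(select_dose_window(single), class = "druggrade_error_too_few_doses")
  expect_error(select_dose_window(tibble::tibble(gr = 1, fv = 1)),
               class = "druggrade_error_too_few_doses")
  constant <- tibble::tibble(gr = c(0.5, 0.5, 0.5), fv = c(0.9, 0.8, 0.7))
  expect_error(compute_grade(constant, m_max = 0.6),
               class = "druggrade_error_degenerate_fit")
})

test_that("pure arrest scores 0 and the death-only boundary scores ~100", {
  m_max <- compute_m_max(0.03, 72)
  arrest <- tibble::tibble(gr = seq(0, 1, length.out = 6), fv = rep(1, 6))
  g0 <- compute_grade(arrest, m_max = m_max)
  expect_equal(g0$grade, 0)
  expect_equal(g0$m_drug, 0)

  boundary <- simulate_response(1, seq(0.05, 0.95, length.out = 8),
                                t_c = 0.03, duration = 72)
  g100 <- compute_grade(boundary, m_max = m_max)
  expect_equal(g100$grade, 100, tolerance = 0.02)
})

test_that("angle-interpolated profiles recover their constructed death fraction", {
  m_max <- compute_m_max(0.03, 72)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    g <- compute_grade(death_fraction_profile(f, 0.03, 72), m_max = m_max)
    expect_equal(g$grade, 100 * f, tolerance = 3)
  }
})

test_that("GRADE rises strictly with the death-rate scale at fixed growth inhibition", {
  m_max <- compute_m_max(0.03, 72)
  g_rel <- c(1, 0.9, 0.75, 0.6, 0.45, 0.3)
  base_d <- c(0, 0.05, 0.12, 0.2, 0.3, 0.4)
  grades <- sapply(c(0.25, 0.5, 1, 1.5, 2), function(s) {
    pts <- simulate_response(g_rel, s * base_d, t_c = 0.03, duration = 72)
    compute_grade(pts, m_max = m_max)$grade
  })
  expect_true(all(diff(grades) > 0))
})

test_that("any region-b profile scores within [0, 100] without clamping", {
  m_max <- compute_m_max(0.03, 72)
  set.seed(7)
  for (i in 1:25) {
    g_end <- runif(1, 0, 1)
    d_end <- runif(1, 0.1, 1.2)
    s <- seq(0, 1, length.out = 8)
    pts <- simulate_response(1 - s * (1 - g_end), s * d_end,
                             t_c = 0.03, duration = 72)
    g <- tryCatch(compute_grade(pts, m_max = m_max), error = function(e) NULL)
    if (is.null(g)) next
    raw <- 100 * atan(g$m_drug) / atan(g$m_max)
    expect_gte(raw, -1e-6)
    expect_lte(raw, 100 + 1e-6)
  }
})

test_that("scoring is invariant to dose ordering and dose-unit rescaling", {
  sc <- scenario_presets()$mixed
  tc <- generate_counts(sc, seed = 5, noise = list(poisson_counts = FALSE))
  prof <- assemble_profile(tc, at_time = 72)
  g1 <- compute_grade(prof)
  reversed <- tibble::as_tibble(prof)[rev(seq_len(nrow(prof))), ]
  g2 <- compute_grade(reversed, m_max = g1$m_max)
  expect_equal(g2$grade, g1$grade)
  rescaled <- dplyr::mutate(prof, dose = dose * 1e3)
  g3 <- compute_grade(rescaled, m_max = g1$m_max)
  expect_equal(g3$grade, g1$grade)
})

test_that("pooling one profile reduces to compute_grade and duplicates are invariant", {
  m_max <- compute_m_max(0.03, 72)
  tc <- generate_counts(scenario_presets()$mixed, seed = 8,
                        noise = list(poisson_counts = FALSE))
  prof <- assemble_profile(tc, at_time = 72)
  single <- pooled_class_grade(list(prof), m_max = m_max)
  expect_equal(single$grade, compute_grade(prof, m_max = m_max)$grade)
  doubled <- pooled_class_grade(list(prof, prof), m_max = m_max)
  expect_equal(doubled$grade, single$grade)
})

test_that("pooled fits equal an independent least squares on concatenated points", {
  m_max <- compute_m_max(0.03, 72)
  tc1 <- generate_counts(scenario_presets()$mixed, seed = 9,
                         noise = list(poisson_counts = FALSE))
  tc2 <- generate_counts(scenario_presets()$death_only_proliferating, seed = 9,
                         noise = list(poisson_counts = FALSE))
  p1 <- assemble_profile(tc1, at_time = 72)
  p2 <- assemble_profile(tc2, at_time = 72)
  pooled <- pooled_class_grade(list(p1, p2), m_max = m_max)
  pts <- dplyr::bind_rows(select_dose_window(p1), select_dose_window(p2))
  slope <- unname(coef(lm(fv ~ gr, data = pts))[2])
  expect_equal(pooled$m_drug, slope, tolerance = 1e-12)
  expect_equal(pooled$grade, 100 * atan(slope) / atan(m_max), tolerance = 1e-9)

  means <- pooled_class_grade(list(p1, p2), m_max = m_max, method = "mean")
  g1 <- compute_grade(p1, m_max = m_max)$grade
  g2 <- compute_grade(p2, m_max = m_max)$grade
  expect_equal(means$grade, mean(c(g1, g2)))

  attr(p2, "cell_line") <- "other"
  expect_error(pooled_class_grade(list(p1, p2), m_max = m_max),
               class = "druggrade_error_domain")
})

test_that("GRADE over time flags pre-onset evaluations and stays 0 for pure arrest", {
  # death-only drug whose killing starts only at 30 h
  onset <- 30
  times <- seq(0, 72, by = 6)
  d_rel <- c(0.3, 0.5, 0.7, 0.9)
  doses <- 1e-7 * 10^(0:3)
  rows <- purrr::map_dfr(seq_along(doses), function(i) {
    purrr::map_dfr(times, function(tt) {
      if (tt <= onset) {
        live <- 2500 * 2^(0.03 * tt)
        dead <- 0
      } else {
        s <- simulate_response(1, d_rel[i], t_c = 0.03, duration = tt - onset,
                               c0 = 2500 * 2^(0.03 * onset))
        live <- s$c_live
        dead <- s$c_dead
      }
      tibble::tibble(dose = doses[i], time = tt, live = live, dead = dead)
    })
  })
  veh <- tibble::tibble(dose = 0, time = times, live = 2500 * 2^(0.03 * times),
                        dead = 0)
  tc <- as_grade_timecourses(dplyr::bind_rows(veh, rows) |>
                               dplyr::mutate(drug = "lagged", cell_line = "syn",
                                             replicate = 1L))
  res <- grade_over_time(tc, times = c(12, 48, 60, 72))
  expect_true("early_timepoint" %in% res$flags[[1]])
  expect_true(all(!is.na(res$grade[res$time >= 48])))

  arrest <- generate_counts(scenario_presets()$arrest_only, seed = 2,
                            noise = list(poisson_counts = FALSE))
  res0 <- grade_over_time(arrest, times = c(24, 48, 72))
  expect_equal(res0$grade, rep(0, 3))
  expect_equal(attr(res0, "stability_48_72"), 0)
})

test_that("grade results tidy into one-row tables", {
  g <- compute_grade(death_fraction_profile(0.5), m_max = compute_m_max(0.03, 72))
  td <- tidy(g)
  expect_equal(nrow(td), 1)
  expect_equal(td$grade, 50, tolerance = 1e-9)
  expect_false(glance(g)$clamped)
})
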