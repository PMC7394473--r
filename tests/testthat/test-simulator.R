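test_that("untreated and arrest-only scenarios match closed forms", {
  unt <- simulate_point(t_c = 0.02, t_d = 0.02, death_rate = 0, duration = 72)
  expect_equal(unt$fv, 1)
  expect_equal(unt$rv, 1)
  expect_equal(unt$gr, 1)

  arr <- simulate_point(t_c = 0.03, t_d = 0, death_rate = 0, duration = 72)
  expect_equal(arr$fv, 1)
  expect_equal(arr$gr, 0, tolerance = 1e-12)
  expect_equal(arr$rv, 2^(-0.03 * 72), tolerance = 1e-12)
})

test_that("dead-cell accumulation matches numerical quadrature of the death flux", {
  cases <- list(c(t_d = 0.03, d = 0.02), c(t_d = 0.01, d = 0.005),
                c(t_d = 0.0209820001, d = 0.03 * log(2) * 1.00000001)) # k ~ 0
  for (cs in cases) {
    sp <- simulate_point(t_c = 0.03, t_d = cs[["t_d"]], death_rate = cs[["d"]],
                         duration = 72, c0 = 100)
    k <- cs[["t_d"]] * log(2) - cs[["d"]]
    oracle <- stats::integrate(function(s) cs[["d"]] * 100 * exp(k * s), 0, 72,
                               rel.tol = 1e-12)$value
    expect_equal(sp$c_dead, oracle, tolerance = 1e-6)
  }
})

test_that("counts stay non-negative and respond monotonically to the rates", {
  d <- seq(0, 0.03, length.out = 15)
  sweep_d <- simulate_point(t_c = 0.03, t_d = 0.02, death_rate = d, duration = 72)
  expect_true(all(sweep_d$c_live > 0 & sweep_d$c_dead >= 0 & sweep_d$c_ctrl > 0))
  expect_true(all(diff(sweep_d$c_dead) > 0))
  expect_true(all(diff(sweep_d$fv) < 0))
  expect_true(all(diff(sweep_d$gr) < 0))

  td <- seq(0, 0.03, length.out = 15)
  sweep_g <- simulate_point(t_c = 0.03, t_d = td, death_rate = 0.005, duration = 72)
  expect_true(all(diff(sweep_g$gr) > 0))
})

test_that("FV and GR are independent of the seeding density", {
  a <- simulate_point(0.03, 0.015, 0.01, 72, c0 = 1e2)
  b <- simulate_point(0.03, 0.015, 0.01, 72, c0 = 1e5)
  expect_equal(a$fv, b$fv, tolerance = 1e-12)
  expect_equal(a$gr, b$gr, tolerance = 1e-12)
  expect_equal(a$rv, b$rv, tolerance = 1e-12)
})

test_that("the simulated grid has the expected boundary structure", {
  g <- simulate_grid(t_c = 0.03, duration = 72, n_growth = 30, n_death = 30)
  no_death <- dplyr::filter(g$grid, d_rel == 0)
  expect_equal(no_death$fv, rep(1, nrow(no_death)))
  death_only <- dplyr::arrange(g$boundaries$death_only, d_rel)
  expect_true(all(diff(death_only$fv) < 0))
  expect_true(all(diff(death_only$gr) < 0))
  expect_error(simulate_grid(t_c = -1, duration = 72),
               class = "druggrade_error_domain")
})

test_that("every simulated response lies in the attainable region b", {
  g <- simulate_grid(t_c = 0.03, duration = 72, n_growth = 40, n_death = 40,
                     d_rel_max = 1.5)
  expect_true(all(in_region_b(g$grid$gr, g$grid$fv, t_c = 0.03, duration = 72)))
})

test_that("m_max equals the steepest per-scenario window slope (brute force)", {
  t_c <- 0.03
  dur <- 72
  m <- compute_m_max(t_c, dur)
  expect_gt(m, 0)
  # brute force: dose-response "rays" scaling each (growth, death) endpoint
  # from no effect to full effect; the windowed FV-vs-GR slope of any ray
  # must peak on the death-only ray (g_end = 1)
  slopes <- purrr::pmap_dbl(
    expand.grid(g_end = seq(0, 1, by = 0.2), d_end = seq(0.2, 1.4, by = 0.2)),
    function(g_end, d_end) {
      s <- seq(0, 1, length.out = 60)
      pts <- simulate_response(1 - s * (1 - g_end), s * d_end,
                               t_c = t_c, duration = dur)
      pts <- dplyr::filter(pts, gr >= 0, gr <= 1)
      if (nrow(pts) < 3 || stats::var(pts$gr) == 0) return(NA_real_)
      stats::coef(stats::lm(fv ~ gr, data = pts))[2]
    })
  expect_equal(max(slopes, na.rm = TRUE), m, tolerance = 0.01)
  expect_error(compute_m_max(t_c, dur, n = 2), class = "druggrade_error_resolution")
})

test_that("m_max grows with proliferation rate and assay length", {
  expect_lt(compute_m_max(0.02, 72), compute_m_max(0.03, 72))
  expect_lt(compute_m_max(0.03, 48), compute_m_max(0.03, 72))
})

test_that("rate inversion recovers the anchor scenarios and round trips", {
  top <- invert_rates(gr = 1, fv = 1, t_c = 0.03, duration = 72)
  expect_equal(c(top$g_rel, top$d_rel), c(1, 0), tolerance = 1e-9)
  arr <- invert_rates(gr = 0, fv = 1, t_c = 0.03, duration = 72)
  expect_equal(c(arr$g_rel, arr$d_rel), c(0, 0), tolerance = 1e-9)

  one <- simulate_response(0.4, 0.3, t_c = 0.03, duration = 72)
  rt <- invert_rates(one$gr, one$fv, t_c = 0.03, duration = 72)
  expect_equal(c(rt$g_rel, rt$d_rel), c(0.4, 0.3), tolerance = 1e-3)
  expect_false(rt$projected)
})

test_that("out-of-region observations are projected and flagged", {
  # region a: population loss far beyond the measured death
  a <- invert_rates(gr = -0.5, fv = 0.999, t_c = 0.03, duration = 72)
  expect_equal(a$region, "a")
  expect_true(a$projected)
  expect_equal(a$g_rel, 0)
  # region c: death offset by super-normal proliferation
  cc <- invert_rates(gr = 0.9, fv = 0.5, t_c = 0.03, duration = 72)
  expect_equal(cc$region, "c")
  expect_equal(cc$g_rel, 1)
  expect_error(invert_rates(gr = 0.5, fv = 0, t_c = 0.03, duration = 72),
               class = "druggrade_error_domain")
})
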