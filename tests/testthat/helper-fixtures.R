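# Shared fixtures, all generated in code.

# Noise-free count table for explicit per-dose rates (bypasses scenario
# monotonicity checks so tests can use arbitrary ladders).
make_timecourses <- function(g_rel, d_rel, doses = 1e-8 * 10^(seq_along(g_rel) / 2),
                             t_c = 0.03, times = seq(0, 72, by = 8), c0 = 2500,
                             drug = "test", cell_line = "syn", replicate = 1L) {
  stopifnot(length(g_rel) == length(d_rel), length(doses) == length(g_rel))
  g_all <- c(1, g_rel)
  d_all <- c(0, d_rel)
  dose_all <- c(0, doses)
  rows <- lapply(seq_along(dose_all), function(i) {
    counts <- lapply(times, function(tt) {
      if (tt == 0) {
        c(live = c0, dead = 0)
      } else {
        s <- simulate_response(g_all[i], d_all[i], t_c = t_c, duration = tt, c0 = c0)
        c(live = s$c_live, dead = s$c_dead)
      }
    })
    counts <- do.call(rbind, counts)
    tibble::tibble(drug = drug, cell_line = cell_line, dose = dose_all[i],
                   replicate = replicate, time = times,
                   live = counts[, "live"], dead = counts[, "dead"])
  })
  as_grade_timecourses(dplyr::bind_rows(rows))
}

# Minimal 6-row CSV fixture: one drug, 2 doses x 3 times.
write_fixture_csv <- function(path, drop = NULL) {
  df <- data.frame(
    drug = "drugA", cell_line = "u2os",
    dose_M = rep(c(0, 1e-6), each = 3),
    time_h = rep(c(24, 48, 72), 2),
    live = c(1200, 1900, 3100, 900, 1100, 1300),
    dead = c(10, 15, 20, 200, 350, 500),
    replicate = 1L
  )
  if (!is.null(drop)) df[[drop]] <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  path
}
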