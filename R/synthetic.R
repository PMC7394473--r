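#' Named dose-response scenarios with known ground truth
#'
#' Five canonical drug behaviours, each an 8-point half-log dose ladder
#' (10 nM to 31.6 uM) with per-dose relative proliferation (`g_rel`) and
#' death (`d_rel`) rates:
#' * `arrest_only` - dose-dependent slowing of proliferation, no death
#'   (CDK4/6-inhibitor-like); ground-truth GRADE 0.
#' * `death_only_proliferating` - death at the untreated proliferation rate
#'   (fast apoptotic agents such as BH3 mimetics); ground-truth GRADE 100.
#' * `biphasic` - arrest at low doses, death only after full arrest
#'   (camptothecin/abemaciclib-like, typical of DNA damagers).
#' * `mixed` - coincident partial arrest and partial death (the most common
#'   experimental pattern); intermediate GRADE.
#' * `non_functional` - essentially no response at any dose; scoring it
#'   must be refused.
#'
#' Defaults mirror a standard imaging experiment: 2,500 cells seeded,
#' control rate 0.03 doublings/hour, samples every 8 h for 72 h, Poisson
#' counting noise, 3 replicates.
#'
#' @return Named list of `grade_scenario` objects with fields `name`,
#'   `doses` (molar), `g_rel`, `d_rel`, `t_c`, `c0`, `sample_times`,
#'   `noise` (list: `poisson_counts`, `lognormal_cv`), `replicates`.
#' @examples
#' names(scenario_presets())
#' @export
scenario_presets <- function() {
  doses <- 1e-8 * 10^(seq(0, 3.5, by = 0.5))
  base <- function(name, g_rel, d_rel) {
    structure(list(name = name, doses = doses, g_rel = g_rel, d_rel = d_rel,
                   t_c = 0.03, c0 = 2500,
                   sample_times = seq(0, 72, by = 8),
                   noise = list(poisson_counts = TRUE, lognormal_cv = 0),
                   replicates = 3L),
              class = "grade_scenario")
  }
  list(
    arrest_only = base("arrest_only",
                       g_rel = c(1.00, 0.92, 0.75, 0.50, 0.28, 0.12, 0.04, 0.01),
                       d_rel = rep(0, 8)),
    death_only_proliferating = base("death_only_proliferating",
                                    g_rel = rep(1, 8),
                                    d_rel = c(0.02, 0.08, 0.20, 0.40, 0.60, 0.78, 0.92, 0.99)),
    biphasic = base("biphasic",
                    g_rel = c(1.00, 0.90, 0.55, 0.20, 0.05, 0.00, 0.00, 0.00),
                    d_rel = c(0, 0, 0, 0, 0, 0.15, 0.45, 0.80)),
    mixed = base("mixed",
                 g_rel = c(1.00, 0.93, 0.80, 0.62, 0.45, 0.30, 0.18, 0.10),
                 d_rel = c(0.00, 0.04, 0.12, 0.25, 0.40, 0.55, 0.70, 0.82)),
    non_functional = base("non_functional",
                          g_rel = c(1, 1, 0.99, 0.99, 0.98, 0.98, 0.97, 0.97),
                          d_rel = c(0, 0, 0.005, 0.005, 0.01, 0.01, 0.015, 0.015))
  )
}

#' Build a custom scenario
#'
#' @param name Scenario label.
#' @param doses Molar dose ladder (ascending, no 0; the vehicle series is
#'   always generated).
#' @param g_rel Per-dose relative proliferation rate, non-increasing with
#'   dose, in \[0, 1\].
#' @param d_rel Per-dose relative death rate, non-decreasing with dose,
#'   >= 0.
#' @param t_c Control proliferation rate (doublings/hour).
#' @param c0 Seeded cells per well.
#' @param sample_times Imaging times (hours, ascending from 0).
#' @param noise List with `poisson_counts` (logical) and `lognormal_cv`
#'   (coefficient of variation of optional multiplicative lognormal noise;
#'   0 disables it).
#' @param replicates Wells per dose.
#' @return A `grade_scenario`.
#' @export
grade_scenario <- function(name, doses, g_rel, d_rel, t_c = 0.03, c0 = 2500,
                           sample_times = seq(0, 72, by = 8),
                           noise = list(poisson_counts = TRUE, lognormal_cv = 0),
                           replicates = 3L) {
  stopifnot(length(doses) == length(g_rel), length(doses) == length(d_rel),
            all(doses > 0), !is.unsorted(doses), t_c > 0, c0 > 0)
  if (is.unsorted(rev(g_rel))) {
    rlang::abort("`g_rel` must be non-increasing with dose.", class = "druggrade_error_domain")
  }
  if (is.unsorted(d_rel)) {
    rlang::abort("`d_rel` must be non-decreasing with dose.", class = "druggrade_error_domain")
  }
  noise <- utils::modifyList(list(poisson_counts = TRUE, lognormal_cv = 0), noise)
  structure(list(name = name, doses = doses, g_rel = g_rel, d_rel = d_rel,
                 t_c = t_c, c0 = c0, sample_times = sample_times,
                 noise = noise, replicates = as.integer(replicates)),
            class = "grade_scenario")
}

#' Generate noisy live/dead count time courses from a scenario
#'
#' Expected live and dead counts at every (dose, time) come from the
#' birth-death model ([simulate_response()]); observation noise is then
#' applied per well: Poisson resampling of each count (imaging counts are
#' object counts) followed by optional multiplicative lognormal noise with
#' the given CV. A vehicle series (dose 0, untreated rates) is always
#' included. Output is deterministic for a given `seed`. Dead counts
#' accumulate without clearance, as dead-cell stains persist in imaging.
#'
#' @param scenario A `grade_scenario` (see [scenario_presets()],
#'   [grade_scenario()]).
#' @param seed Integer seed for the noise draws.
#' @param replicates Override the scenario's replicate count.
#' @param noise Override the scenario's noise settings (list with
#'   `poisson_counts` and/or `lognormal_cv`; e.g.,
#'   `list(poisson_counts = FALSE)` for noise-free expectations).
#' @return A `grade_timecourses` tibble (see [read_timecourses()]).
#' @examples
#' tc <- generate_counts(scenario_presets()$biphasic, seed = 7)
#' @export
generate_counts <- function(scenario, seed = 1L, replicates = NULL, noise = NULL) {
  if (!inherits(scenario, "grade_scenario")) {
    rlang::abort("`scenario` must be a grade_scenario (see scenario_presets()).",
                 class = "druggrade_error_domain")
  }
  replicates <- if (is.null(replicates)) scenario$replicates else as.integer(replicates)
  ns <- scenario$noise
  if (!is.null(noise)) ns <- utils::modifyList(ns, noise)

  design <- tidyr::expand_grid(
    dose_idx = seq(0, length(scenario$doses)), # 0 = vehicle
    replicate = seq_len(replicates),
    time = scenario$sample_times
  )
  g_rel <- c(1, scenario$g_rel)[design$dose_idx + 1]
  d_rel <- c(0, scenario$d_rel)[design$dose_idx + 1]
  dose <- c(0, scenario$doses)[design$dose_idx + 1]

  live <- numeric(nrow(design))
  dead <- numeric(nrow(design))
  for (tt in unique(design$time)) {
    idx <- which(design$time == tt)
    if (tt == 0) {
      live[idx] <- scenario$c0
      dead[idx] <- 0
    } else {
      sim <- simulate_response(g_rel[idx], d_rel[idx], t_c = scenario$t_c,
                               duration = tt, c0 = scenario$c0)
      live[idx] <- sim$c_live
      dead[idx] <- sim$c_dead
    }
  }
  withr::with_seed(as.integer(seed), {
    if (isTRUE(ns$poisson_counts)) {
      live <- stats::rpois(length(live), live)
      dead <- stats::rpois(length(dead), dead)
    }
    cv <- ns$lognormal_cv
    if (is.numeric(cv) && cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      live <- live * stats::rlnorm(length(live), -sdlog^2 / 2, sdlog)
      dead <- dead * stats::rlnorm(length(dead), -sdlog^2 / 2, sdlog)
    }
  })

  as_grade_timecourses(tibble::tibble(
    drug = scenario$name, cell_line = "synthetic",
    dose = dose, replicate = design$replicate,
    time = design$time, live = live, dead = dead
  ))
}
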