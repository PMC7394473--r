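#' Assemble a dose-response profile of RV/FV/GR at one time point
#'
#' Collapses well-level count time courses for one drug on one cell line
#' into a per-dose table of the three endpoint metrics. Counts are averaged
#' across replicates first and the metrics computed on the mean counts
#' (which stabilises FV when dead counts are small); per-replicate metrics
#' are kept only to report dispersion (SD across replicates). The control
#' proliferation rate is estimated from the vehicle series with
#' [fit_growth_curve()]. When `at_time` falls between sampled frames, counts
#' are interpolated linearly in time (negligible error at 6-8 h sampling).
#'
#' @param timecourses A `grade_timecourses` table (see [read_timecourses()])
#'   for a single (drug, cell line) batch, including a dose == 0 vehicle
#'   series.
#' @param at_time Endpoint in hours; must lie within the observed time range.
#' @param t0_live Live count at treatment start (e.g., from a day-0 control
#'   plate). If `NULL`, the mean vehicle live count at time 0 is used.
#' @param normalize_basal If `TRUE`, rescale FV to the vehicle FV via
#'   [normalize_fv_basal()] (for cell lines with high basal death). Default
#'   uses raw FV.
#' @return A `dose_response_profile` tibble, one row per non-zero dose
#'   (ascending), with columns `dose`, `rv`, `fv`, `gr`, `lethal_fraction`,
#'   `rv_sd`, `fv_sd`, `gr_sd`, `n_reps`, and attributes `drug`,
#'   `cell_line`, `assay_duration`, `control_doubling_rate`, `t0_live`,
#'   `fv_vehicle`.
#' @examples
#' sc <- scenario_presets()$mixed
#' tc <- generate_counts(sc, seed = 1, noise = list(poisson_counts = FALSE))
#' assemble_profile(tc, at_time = 72)
#' @export
assemble_profile <- function(timecourses, at_time, t0_live = NULL,
                             normalize_basal = FALSE) {
  tc <- as_grade_timecourses(timecourses)
  batch <- dplyr::distinct(tc, .data$drug, .data$cell_line)
  if (nrow(batch) > 1) {
    rlang::abort("`timecourses` must contain a single (drug, cell_line) batch; split and map over batches.",
                 class = "druggrade_error_domain")
  }
  if (!any(tc$dose == 0)) {
    rlang::abort("no vehicle (dose == 0) series present; RV and GR need a control reference.",
                 class = "druggrade_error_no_vehicle")
  }
  doses <- sort(unique(tc$dose[tc$dose > 0]))
  if (length(doses) < 2) {
    rlang::abort("fewer than 2 non-vehicle doses; GRADE should not be calculated from single doses.",
                 class = "druggrade_error_too_few_doses")
  }
  rng <- range(tc$time)
  if (at_time < rng[1] || at_time > rng[2]) {
    rlang::abort(sprintf("`at_time` = %g h is outside the observed range [%g, %g] h.",
                         at_time, rng[1], rng[2]),
                 class = "druggrade_error_time_range")
  }

  # per-well counts at the endpoint (linear interpolation between frames)
  at_endpoint <- tc |>
    dplyr::group_by(.data$dose, .data$replicate) |>
    dplyr::summarise(
      live = interp_count(.data$time, .data$live, at_time),
      dead = interp_count(.data$time, .data$dead, at_time),
      .groups = "drop"
    )

  # replicate-mean counts per dose; metrics of means
  by_dose <- at_endpoint |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(live = mean(.data$live), dead = mean(.data$dead),
                     n_reps = dplyr::n(), .groups = "drop")
  vehicle <- dplyr::filter(by_dose, .data$dose == 0)

  # t0 reference: explicit day-0 count, else mean vehicle live count at t = 0
  if (is.null(t0_live)) {
    t0_rows <- dplyr::filter(tc, .data$dose == 0, .data$time == 0)
    if (nrow(t0_rows) == 0) {
      rlang::abort("no t = 0 vehicle sample found; supply `t0_live` from a day-0 measurement.",
                   class = "druggrade_error_domain")
    }
    t0_live <- mean(t0_rows$live)
  }
  stopifnot(t0_live > 0)

  # control proliferation rate from the replicate-mean vehicle series
  veh_series <- tc |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(live = mean(.data$live), .groups = "drop")
  growth <- fit_growth_curve(veh_series$time, veh_series$live)

  fv_vehicle <- fractional_viability(vehicle$live, vehicle$dead)
  treated <- dplyr::filter(by_dose, .data$dose > 0)
  fv <- fractional_viability(treated$live, treated$dead)
  if (normalize_basal) fv <- normalize_fv_basal(fv, fv_vehicle)

  # per-replicate metrics, used only for dispersion
  veh_by_rep <- dplyr::filter(at_endpoint, .data$dose == 0)
  disp <- at_endpoint |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::left_join(veh_by_rep, by = "replicate", suffix = c("", "_veh")) |>
    dplyr::filter(!is.na(.data$live_veh)) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      rv_sd = stats::sd(.data$live / .data$live_veh),
      fv_sd = stats::sd(fractional_viability(.data$live, .data$dead)),
      gr_sd = stats::sd(tryCatch(
        as.numeric(gr_value(.data$live, t0_live, .data$live_veh)),
        error = function(e) rep(NA_real_, length(.data$live))
      )),
      .groups = "drop"
    )

  points <- tibble::tibble(
    dose = treated$dose,
    rv = relative_viability(treated$live, vehicle$live),
    fv = fv,
    gr = as.numeric(gr_value(treated$live, t0_live, vehicle$live)),
    lethal_fraction = 1 - fv,
    n_reps = treated$n_reps
  ) |>
    dplyr::left_join(disp, by = "dose") |>
    dplyr::arrange(.data$dose)

  structure(points,
            class = c("dose_response_profile", class(tibble::tibble())),
            drug = batch$drug, cell_line = batch$cell_line,
            assay_duration = at_time,
            control_doubling_rate = growth$b,
            t0_live = t0_live, fv_vehicle = fv_vehicle)
}

interp_count <- function(times, counts, at_time) {
  ord <- order(times)
  stats::approx(times[ord], counts[ord], xout = at_time, rule = 1)$y
}

#' Write a dose-response profile as tidy CSV
#'
#' @param profile A `dose_response_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- tibble::as_tibble(profile)
  out$drug <- attr(profile, "drug")
  out$cell_line <- attr(profile, "cell_line")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.dose_response_profile <- function(x, ...) {
  cat(sprintf("<dose_response_profile> %s / %s at %g h; control rate %.4f dbl/h\n",
              attr(x, "drug"), attr(x, "cell_line"),
              attr(x, "assay_duration"), attr(x, "control_doubling_rate")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
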