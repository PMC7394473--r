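#' Select the dose window for GRADE fitting
#'
#' GRADE is fitted over doses whose GR lies in \[0, 1\], the range over
#' which the FV-vs-GR relationship is approximately linear and which spans
#' the doses around the conventional IC50. Profiles with fewer than 2 points
#' in the window (e.g., drugs that jump from no response to GR < 0 between
#' consecutive doses) and essentially non-functional drugs (GR and FV above
#' 0.9 at every dose) are rejected rather than silently scored.
#'
#' @param profile A `dose_response_profile`, or any data frame with `gr` and
#'   `fv` columns (one row per dose).
#' @return The rows with GR in \[0, 1\].
#' @export
select_dose_window <- function(profile) {
  if (!all(c("gr", "fv") %in% names(profile))) {
    rlang::abort("`profile` must have `gr` and `fv` columns.",
                 class = "druggrade_error_schema")
  }
  if (nrow(profile) < 2) {
    rlang::abort("profile has fewer than 2 doses; GRADE should not be calculated from single doses.",
                 class = "druggrade_error_too_few_doses")
  }
  if (all(profile$gr > 0.9 & profile$fv > 0.9)) {
    rlang::abort("GR and FV exceed 0.9 at all doses: the drug is essentially non-functional and its GRADE would be noise.",
                 class = "druggrade_error_non_functional")
  }
  window <- dplyr::filter(profile, .data$gr >= 0, .data$gr <= 1)
  if (nrow(window) < 2) {
    rlang::abort(sprintf("only %d dose(s) fall in the GR [0, 1] window; GRADE should not be calculated from single doses.",
                         nrow(window)),
                 class = "druggrade_error_too_few_doses")
  }
  window
}

#' Compute the drug GRADE of a dose-response profile
#'
#' GRADE (growth-rate-adjusted death) scores the fraction of an observed
#' drug response attributable to cell death at IC50-range doses. An ordinary
#' least-squares line is fitted through the (GR, FV) points in the GR
#' \[0, 1\] dose window; its slope `m_drug` is compared, on the angle scale,
#' with the maximal slope `m_max` attainable when the response is pure death
#' in normally proliferating cells (from the birth-death simulation):
#' \deqn{GRADE = 100 \cdot \arctan(m_{drug}) / \arctan(m_{max})}
#' 0 means the response is entirely proliferative inhibition (FV flat at 1);
#' 100 means it is entirely cell death. Slopes outside \[0, m_max\] clamp to
#' 0 or 100 with a `clamped` flag.
#'
#' @param profile A `dose_response_profile` (or data frame with `gr`, `fv`).
#' @param m_max Reference slope from [compute_m_max()]. If `NULL` it is
#'   computed from the profile's `control_doubling_rate` and
#'   `assay_duration` attributes.
#' @return A `grade_result`: list with `grade`, `m_drug`, `m_max`, `theta`
#'   (radians), `intercept`, `n_doses_used`, `dose_window`, `flags`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' pts <- death_fraction_profile(0.5, t_c = 0.03, duration = 72)
#' compute_grade(pts, m_max = compute_m_max(0.03, 72))
#' @export
compute_grade <- function(profile, m_max = NULL) {
  if (is.null(m_max)) {
    t_c <- attr(profile, "control_doubling_rate")
    duration <- attr(profile, "assay_duration")
    if (is.null(t_c) || is.null(duration)) {
      rlang::abort("`m_max` not given and profile carries no control_doubling_rate/assay_duration attributes.",
                   class = "druggrade_error_domain")
    }
    m_max <- compute_m_max(t_c, duration)
  }
  stopifnot(is.numeric(m_max), length(m_max) == 1L)
  if (m_max <= 0) {
    rlang::abort("`m_max` must be positive.", class = "druggrade_error_domain")
  }
  window <- select_dose_window(profile)
  if (stats::var(window$gr) == 0) {
    rlang::abort("zero GR variance in the dose window; the FV-vs-GR slope is undefined.",
                 class = "druggrade_error_degenerate_fit")
  }
  fit <- stats::lm(fv ~ gr, data = window)
  m_drug <- unname(stats::coef(fit)[2])
  raw <- 100 * atan(m_drug) / atan(m_max)
  flags <- character()
  if (raw < 0 || raw > 100) flags <- "clamped"
  structure(
    list(grade = min(max(raw, 0), 100),
         m_drug = m_drug, m_max = m_max, theta = atan(m_drug),
         intercept = unname(stats::coef(fit)[1]),
         n_doses_used = nrow(window),
         dose_window = if ("dose" %in% names(window)) window$dose else NULL,
         drug = attr(profile, "drug"), cell_line = attr(profile, "cell_line"),
         flags = flags),
    class = "grade_result"
  )
}

#' @export
print.grade_result <- function(x, ...) {
  lab <- if (!is.null(x$drug)) paste0(" ", x$drug, if (!is.null(x$cell_line)) paste0(" / ", x$cell_line)) else ""
  cat(sprintf("<grade_result>%s GRADE = %.1f (m_drug = %.4f, m_max = %.4f, n = %d)%s\n",
              lab, x$grade, x$m_drug, x$m_max, x$n_doses_used,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' GRADE as a function of assay time
#'
#' Recomputes GRADE at each requested endpoint from kinetic count data,
#' re-deriving the reference slope `m_max` for each duration (the response
#' space geometry depends on it). GRADEs drift while death is still
#' unfolding and are expected to stabilise by roughly 48 h after drug
#' addition; the returned table carries a stability summary (the maximum
#' absolute GRADE change over the 48-72 h evaluations) as the
#' `"stability_48_72"` attribute.
#'
#' Endpoints evaluated before death onset (maximum lethal fraction below
#' 0.05 across doses) are flagged `early_timepoint` rather than erroring;
#' endpoints whose window cannot be scored yield `NA` with a
#' `not_evaluable` flag.
#'
#' @param timecourses A `grade_timecourses` table for one (drug, cell line)
#'   batch.
#' @param times Endpoints (hours) at which to score (>= 3 for a kinetic
#'   read).
#' @param t0_live Optional day-0 live count (see [assemble_profile()]).
#' @param normalize_basal Passed to [assemble_profile()].
#' @return A tibble with one row per time: `time`, `grade`, `m_drug`,
#'   `m_max`, `n_doses_used`, `flags` (list-column), plus the stability
#'   attribute.
#' @export
grade_over_time <- function(timecourses, times, t0_live = NULL,
                            normalize_basal = FALSE) {
  stopifnot(length(times) >= 1)
  rows <- purrr::map(times, function(tt) {
    tryCatch({
      prof <- assemble_profile(timecourses, at_time = tt, t0_live = t0_live,
                               normalize_basal = normalize_basal)
      early <- if (max(prof$lethal_fraction) < 0.05) "early_timepoint" else NULL
      g <- tryCatch(compute_grade(prof), error = function(e) e)
      if (inherits(g, "error")) {
        # death (or any response) not yet measurable: flagged, not an error
        tibble::tibble(time = tt, grade = NA_real_, m_drug = NA_real_,
                       m_max = NA_real_, n_doses_used = NA_integer_,
                       flags = list(c("not_evaluable", early, conditionMessage(g))))
      } else {
        tibble::tibble(time = tt, grade = g$grade, m_drug = g$m_drug,
                       m_max = g$m_max, n_doses_used = g$n_doses_used,
                       flags = list(c(g$flags, early)))
      }
    }, error = function(e) {
      tibble::tibble(time = tt, grade = NA_real_, m_drug = NA_real_,
                     m_max = NA_real_, n_doses_used = NA_integer_,
                     flags = list(c("not_evaluable", conditionMessage(e))))
    })
  })
  out <- dplyr::bind_rows(rows)
  late <- out$grade[out$time >= 48 & !is.na(out$grade)]
  attr(out, "stability_48_72") <- if (length(late) >= 2) max(late) - min(late) else NA_real_
  out
}

#' Pool several dose-response profiles into one class GRADE
#'
#' Drugs sharing a mechanism of action tend to produce very similar GRADEs
#' within a cell line. This pools the windowed (GR, FV) points of all
#' profiles of a drug class into a single least-squares fit, yielding one
#' GRADE for the class in that cell line. With a single profile it reduces
#' exactly to [compute_grade()].
#'
#' @param profiles List of `dose_response_profile` objects from the same
#'   cell line.
#' @param m_max Reference slope (see [compute_m_max()]).
#' @param method `"pooled"` (one fit over all points, default) or
#'   `"mean"` (mean of per-profile GRADEs).
#' @return A `grade_result` for the class.
#' @export
pooled_class_grade <- function(profiles, m_max, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(is.list(profiles), length(profiles) >= 1)
  lines <- unique(unlist(lapply(profiles, function(p) {
    cl <- attr(p, "cell_line")
    if (is.null(cl)) NA_character_ else cl
  })))
  lines <- lines[!is.na(lines)]
  if (length(lines) > 1) {
    rlang::abort("profiles come from more than one cell line; pool within a single line.",
                 class = "druggrade_error_domain")
  }
  if (method == "mean") {
    grades <- vapply(profiles, function(p) compute_grade(p, m_max = m_max)$grade, 1)
    res <- compute_grade(dplyr::bind_rows(lapply(profiles, select_dose_window)),
                         m_max = m_max)
    res$grade <- mean(grades)
    res$flags <- unique(c(res$flags, "mean_of_grades"))
    return(res)
  }
  pooled <- dplyr::bind_rows(lapply(profiles, select_dose_window))
  res <- compute_grade(pooled, m_max = m_max)
  res$cell_line <- if (length(lines)) lines else NULL
  res$drug <- paste0("class(", length(profiles), " profiles)")
  res
}

#' Reference (GR, FV) profile with a known death fraction
#'
#' Constructs noise-free (GR, FV) points for which cell death contributes
#' exactly fraction `f` of the response, by interpolating on the angle
#' scale between the arrest-only boundary (slope 0) and the fitted
#' death-only slope `m_max`: the points lie on the line through (1, 1) with
#' slope `tan(f * atan(m_max))`, so their GRADE is `100 f` by construction.
#' Useful as ground truth for validating the scoring pipeline.
#'
#' @param f Death fraction in \[0, 1\].
#' @param t_c Control proliferation rate (doublings/hour).
#' @param duration Assay duration (hours).
#' @param n Number of points spanning GR \[0, 1\].
#' @return Tibble with `gr` and `fv` columns.
#' @export
death_fraction_profile <- function(f, t_c = 0.03, duration = 72, n = 8) {
  stopifnot(f >= 0, f <= 1, n >= 2)
  m_max <- compute_m_max(t_c, duration)
  m_f <- tan(f * atan(m_max))
  gr <- seq(0, 1, length.out = n)
  tibble::tibble(gr = gr, fv = 1 + m_f * (gr - 1))
}
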