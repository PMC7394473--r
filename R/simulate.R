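#' Simulate one drug response under the exponential birth-death model
#'
#' Deterministic expectations for a well treated at time 0 and observed at
#' `duration` hours. Untreated cells grow exponentially at `t_c` doublings
#' per hour with no death; treated cells grow at `t_d <= t_c` and die at a
#' constant average per-capita rate `death_rate` per hour:
#' \deqn{C_{ctrl} = C_0 \, 2^{t_c t}, \quad
#'       C_{live} = C_0 e^{k t}, \; k = t_d \ln 2 - D_R, \quad
#'       C_{dead} = C_0 D_R (e^{k t} - 1)/k}
#' with the limit \eqn{C_0 D_R t} as \eqn{k \to 0}. Dead cells accumulate
#' without clearance, matching a cumulative dead-cell imaging readout.
#' FV, RV and GR are derived from these counts and `c0`.
#'
#' @param t_c Control proliferation rate (doublings/hour).
#' @param t_d Drug-treated proliferation rate (doublings/hour),
#'   `0 <= t_d <= t_c`.
#' @param death_rate Average per-capita death rate of treated cells
#'   (per hour, >= 0). Control death is taken as zero.
#' @param duration Assay duration in hours.
#' @param c0 Initial live cell count.
#' @return A one-row tibble with `c_ctrl`, `c_live`, `c_dead`, `fv`, `rv`,
#'   `gr` (vectorised over `t_d` / `death_rate`).
#' @seealso [simulate_response()] for the relative-rate parameterisation,
#'   [simulate_grid()], [invert_rates()].
#' @examples
#' simulate_point(t_c = 0.03, t_d = 0, death_rate = 0, duration = 72)
#' @export
simulate_point <- function(t_c, t_d, death_rate, duration, c0 = 2500) {
  stopifnot(t_c > 0, duration > 0, c0 > 0)
  if (any(t_d < 0) || any(t_d > t_c + 1e-12)) {
    rlang::abort("`t_d` must satisfy 0 <= t_d <= t_c.", class = "druggrade_error_domain")
  }
  if (any(death_rate < 0)) {
    rlang::abort("`death_rate` must be non-negative.", class = "druggrade_error_domain")
  }
  n <- max(length(t_d), length(death_rate))
  t_d <- rep_len(t_d, n)
  death_rate <- rep_len(death_rate, n)

  k <- t_d * log(2) - death_rate
  c_ctrl <- c0 * 2^(t_c * duration)
  c_live <- c0 * exp(k * duration)
  # integral of D_R * C_live over [0, duration]; series limit near k = 0
  growth_integral <- ifelse(abs(k) * duration < 1e-9,
                            duration * (1 + k * duration / 2),
                            (exp(k * duration) - 1) / k)
  c_dead <- c0 * death_rate * growth_integral

  fv <- c_live / (c_live + c_dead)
  rv <- c_live / c_ctrl
  gr <- 2^(log2(c_live / c0) / log2(c_ctrl / c0)) - 1
  tibble::tibble(c_ctrl = c_ctrl, c_live = c_live, c_dead = c_dead,
                 fv = fv, rv = rv, gr = gr)
}

#' Simulate a response on the relative-rate scale
#'
#' Convenience wrapper over [simulate_point()] taking rates relative to the
#' untreated proliferation rate: `g_rel = t_d / t_c` in \[0, 1\] and
#' `d_rel = D_R / (t_c ln 2)`, so that `d_rel = 1` is death consuming exactly
#' the untreated growth (GR = 0 on the death-only boundary). On this scale
#' \eqn{GR = 2^{g_{rel} - d_{rel}} - 1}.
#'
#' @param g_rel Relative proliferation rate(s) in \[0, 1\].
#' @param d_rel Relative death rate(s), >= 0.
#' @inheritParams simulate_point
#' @return Tibble as [simulate_point()], with `g_rel` and `d_rel` columns
#'   prepended.
#' @export
simulate_response <- function(g_rel, d_rel, t_c = 0.03, duration = 72, c0 = 2500) {
  n <- max(length(g_rel), length(d_rel))
  g_rel <- rep_len(g_rel, n)
  d_rel <- rep_len(d_rel, n)
  out <- simulate_point(t_c = t_c, t_d = g_rel * t_c,
                        death_rate = d_rel * t_c * log(2),
                        duration = duration, c0 = c0)
  dplyr::bind_cols(tibble::tibble(g_rel = g_rel, d_rel = d_rel), out)
}

#' Simulate the full (GR, FV) response space
#'
#' Evaluates the birth-death model over a dense grid of relative growth
#' rates (`g_rel` in \[0, 1\]) and relative death rates (`d_rel` in
#' \[0, `d_rel_max`\]), the space of all combinations of growth inhibition
#' and cell death. Three boundary responses delimit the attainable region
#' ("region b") of the (GR, FV) plane:
#' * arrest-only (`d_rel = 0`): FV stays 1 while GR falls;
#' * death-only (`g_rel = 1`): death in normally proliferating cells, the
#'   right/lower boundary and the steepest attainable FV-vs-GR relationship;
#' * biphasic (`g_rel = 0`): death within fully arrested cells, the left
#'   boundary.
#'
#' @param t_c Control proliferation rate (doublings/hour).
#' @param duration Assay duration (hours).
#' @param n_growth,n_death Grid resolution per axis (>= 25).
#' @param d_rel_max Upper end of the relative death-rate axis.
#' @param c0 Initial cell count (affects raw counts only, not FV/RV/GR).
#' @return An object of class `grade_simgrid`: list with `grid` (tibble of
#'   `g_rel`, `d_rel`, `fv`, `rv`, `gr`), `boundaries` (named list of
#'   tibbles `arrest_only`, `death_only`, `biphasic`), `m_max`, `t_c`,
#'   `duration`.
#' @examples
#' g <- simulate_grid(t_c = 0.03, duration = 72, n_growth = 25, n_death = 25)
#' g$m_max
#' @export
simulate_grid <- function(t_c, duration, n_growth = 50, n_death = 50,
                          d_rel_max = 1, c0 = 2500) {
  if (!is.numeric(t_c) || t_c <= 0) {
    rlang::abort("`t_c` must be positive.", class = "druggrade_error_domain")
  }
  stopifnot(n_growth >= 25, n_death >= 25, d_rel_max > 0)
  axes <- tidyr::expand_grid(g_rel = seq(0, 1, length.out = n_growth),
                             d_rel = seq(0, d_rel_max, length.out = n_death))
  grid <- simulate_response(axes$g_rel, axes$d_rel, t_c = t_c,
                            duration = duration, c0 = c0)
  boundary <- function(df) dplyr::select(df, "g_rel", "d_rel", "fv", "rv", "gr")
  boundaries <- list(
    arrest_only = boundary(dplyr::filter(grid, .data$d_rel == 0)),
    death_only  = boundary(dplyr::filter(grid, .data$g_rel == 1)),
    biphasic    = boundary(dplyr::filter(grid, .data$g_rel == 0))
  )
  structure(
    list(grid = dplyr::select(grid, "g_rel", "d_rel", "fv", "rv", "gr"),
         boundaries = boundaries,
         m_max = compute_m_max(t_c, duration),
         t_c = t_c, duration = duration),
    class = "grade_simgrid"
  )
}

#' @export
print.grade_simgrid <- function(x, ...) {
  cat(sprintf(
    "<grade_simgrid> %d points; t_c = %g dbl/h, duration = %g h, m_max = %.4f\n",
    nrow(x$grid), x$t_c, x$duration, x$m_max))
  invisible(x)
}

#' Maximal FV-vs-GR slope (m_max)
#'
#' The reference slope for GRADE scoring: the slope of the FV-vs-GR
#' relationship when an observed response is due entirely to cell death in
#' normally proliferating cells. The death-only boundary (`g_rel = 1`) is
#' sampled with the death rate swept so that GR spans \[0, 1\], and an
#' ordinary least-squares line of FV on GR is fitted over that window,
#' mirroring how a drug's own slope `m_drug` is fitted. m_max depends on the
#' control proliferation rate and the assay duration, so it is recomputed
#' per experiment rather than cached.
#'
#' @inheritParams simulate_grid
#' @param n Number of death-rate samples along the boundary (>= 3 must land
#'   in GR between 0 and 1).
#' @return Positive slope (FV units per GR unit); independent of `c0`.
#' @examples
#' compute_m_max(t_c = 0.03, duration = 72)
#' @export
compute_m_max <- function(t_c, duration, n = 201) {
  if (!is.numeric(t_c) || t_c <= 0 || !is.numeric(duration) || duration <= 0) {
    rlang::abort("`t_c` and `duration` must be positive.", class = "druggrade_error_domain")
  }
  # d_rel in [0, 1] sweeps GR from 1 (no death) down to 0 exactly
  pts <- simulate_response(g_rel = 1, d_rel = seq(0, 1, length.out = n),
                           t_c = t_c, duration = duration)
  pts <- dplyr::filter(pts, .data$gr >= 0, .data$gr <= 1)
  if (nrow(pts) < 3) {
    rlang::abort("fewer than 3 boundary samples landed in GR [0, 1]; increase `n`.",
                 class = "druggrade_error_resolution")
  }
  unname(stats::coef(stats::lm(fv ~ gr, data = pts))[2])
}

#' Invert observed (GR, FV) to average proliferation and death rates
#'
#' Maps an observed endpoint (GR, FV) pair back to the average relative
#' proliferation rate `g_rel` and relative death rate `d_rel` of the
#' birth-death model that reproduces it. Under the model the inversion is
#' exact: GR fixes the net rate `k = t_c ln2 log2(1 + GR)`, and FV then
#' fixes the death rate via the dead/live ratio
#' `1/FV - 1 = D_R (1 - e^{-kt})/k`.
#'
#' Rates are reported relative to the untreated proliferation rate (a
#' `d_rel` of 0.05 means death at 5% of the untreated growth rate).
#' Observations outside the attainable region are projected onto its nearest
#' boundary and flagged: region "a" (`g_rel < 0`, population loss exceeding
#' measured death) and region "c" (`g_rel > 1`, death offset by faster
#' proliferation) are theoretical possibilities not produced by the model.
#'
#' @param gr Observed GR value(s), each > -1.
#' @param fv Observed FV fraction(s) in (0, 1\].
#' @param t_c Control proliferation rate (doublings/hour).
#' @param duration Assay duration (hours).
#' @param tol Absolute tolerance on `g_rel` before a point is flagged as
#'   outside region b.
#' @return Tibble with columns `gr`, `fv`, `g_rel`, `d_rel`, `region`
#'   ("a", "b" or "c") and `projected` (logical).
#' @examples
#' invert_rates(gr = 0, fv = 1, t_c = 0.03, duration = 72) # pure arrest
#' @export
invert_rates <- function(gr, fv, t_c, duration, tol = 1e-6) {
  stopifnot(is.numeric(gr), is.numeric(fv), t_c > 0, duration > 0)
  if (any(gr <= -1)) {
    rlang::abort("`gr` must be greater than -1 (finite live population).",
                 class = "druggrade_error_domain")
  }
  if (any(fv <= 0) || any(fv > 1)) {
    rlang::abort("`fv` must lie in (0, 1].", class = "druggrade_error_domain")
  }
  n <- max(length(gr), length(fv))
  gr <- rep_len(gr, n)
  fv <- rep_len(fv, n)

  k <- t_c * log(2) * log2(1 + gr)
  ratio <- 1 / fv - 1 # c_dead / c_live
  decay <- ifelse(abs(k) * duration < 1e-9,
                  duration * (1 - k * duration / 2),
                  (1 - exp(-k * duration)) / k)
  d_abs <- ratio / decay
  d_rel <- d_abs / (t_c * log(2))
  g_rel <- (k + d_abs) / (t_c * log(2))

  region <- dplyr::case_when(g_rel < -tol ~ "a",
                             g_rel > 1 + tol ~ "c",
                             TRUE ~ "b")
  projected <- region != "b"
  g_rel <- pmin(pmax(g_rel, 0), 1)
  d_rel <- pmax(d_rel, 0)
  tibble::tibble(gr = gr, fv = fv, g_rel = g_rel, d_rel = d_rel,
                 region = region, projected = projected)
}

#' Test whether observed (GR, FV) pairs are attainable by the model
#'
#' @inheritParams invert_rates
#' @return Logical vector: TRUE where the pair lies in region b.
#' @export
in_region_b <- function(gr, fv, t_c, duration, tol = 1e-6) {
  invert_rates(gr, fv, t_c = t_c, duration = duration, tol = tol)$region == "b"
}
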