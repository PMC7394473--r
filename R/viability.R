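#' Relative viability (RV)
#'
#' Live cells in the drug-treated condition divided by live cells in the
#' vehicle control at the same time point. RV conflates proliferative arrest
#' with cell death: a half-sized population may be fully alive but slow, or
#' fast-growing but half dead. Values above 1 (growth stimulation) are kept.
#'
#' @param live_treated Live cell count(s) under drug.
#' @param live_ctrl Live cell count(s) in the matched vehicle control
#'   (must be positive).
#' @return Numeric vector of RV fractions.
#' @examples
#' relative_viability(250, 500)
#' @export
relative_viability <- function(live_treated, live_ctrl) {
  stopifnot(is.numeric(live_treated), is.numeric(live_ctrl))
  if (any(live_ctrl <= 0)) {
    rlang::abort("`live_ctrl` must be positive: RV is undefined without a live control population.",
                 class = "druggrade_error_reference")
  }
  live_treated / live_ctrl
}

#' Fractional viability (FV) and lethal fraction
#'
#' Live cells divided by all (live + dead) cells within the treated
#' population. FV directly measures the unkilled fraction and needs no
#' untreated reference; the lethal fraction is its complement, `1 - FV`.
#'
#' @param live,dead Non-negative cell counts; `live + dead` must be positive.
#' @return Numeric vector of FV fractions in \[0, 1\].
#' @examples
#' fractional_viability(250, 250)
#' lethal_fraction(250, 250)
#' @export
fractional_viability <- function(live, dead) {
  stopifnot(is.numeric(live), is.numeric(dead))
  if (any(live < 0) || any(dead < 0)) {
    rlang::abort("counts must be non-negative.", class = "druggrade_error_domain")
  }
  if (any(live + dead == 0)) {
    rlang::abort("`live + dead` must be positive: FV is undefined for an empty population.",
                 class = "druggrade_error_empty_population")
  }
  live / (live + dead)
}

#' @rdname fractional_viability
#' @export
lethal_fraction <- function(live, dead) {
  1 - fractional_viability(live, dead)
}

#' Growth-rate inhibition (GR) value
#'
#' Normalised growth-rate inhibition of the treated population:
#' \deqn{GR = 2^{\log_2(x/x_0)/\log_2(x_{ctrl}/x_0)} - 1}
#' where `x` is the live count at the endpoint under drug, `x0` the live
#' count at treatment start, and `x_ctrl` the endpoint live count in vehicle.
#' GR = 1 for untreated-rate growth, 0 for complete cytostasis, and negative
#' when the population shrank. Unlike RV, GR is insensitive to assay length
#' and to the control proliferation rate.
#'
#' A treated count of exactly zero is returned as the limiting value -1 and
#' recorded in the `"saturated"` attribute rather than as `-Inf`, so that
#' downstream curve fits stay finite.
#'
#' @param x_treated Endpoint live count(s) under drug (>= 0).
#' @param x0 Live count at treatment start (> 0).
#' @param x_ctrl Endpoint live count in vehicle; must exceed `x0`
#'   (the control must have grown).
#' @return Numeric vector of GR values with a logical `"saturated"`
#'   attribute marking entries where `x_treated == 0`.
#' @examples
#' gr_value(100, 100, 400) # complete cytostasis -> 0
#' gr_value(50, 100, 400)  # net population loss -> 2^(-1/2) - 1
#' @export
gr_value <- function(x_treated, x0, x_ctrl) {
  stopifnot(is.numeric(x_treated), is.numeric(x0), is.numeric(x_ctrl))
  if (any(x0 <= 0)) {
    rlang::abort("`x0` must be positive.", class = "druggrade_error_domain")
  }
  if (any(x_ctrl <= x0)) {
    rlang::abort("`x_ctrl` must exceed `x0`: GR is undefined when the control population did not grow.",
                 class = "druggrade_error_no_growth")
  }
  if (any(x_treated < 0)) {
    rlang::abort("`x_treated` must be non-negative.", class = "druggrade_error_domain")
  }
  saturated <- x_treated == 0
  gr <- ifelse(saturated, -1,
               2^(log2(x_treated / x0) / log2(x_ctrl / x0)) - 1)
  attr(gr, "saturated") <- saturated
  gr
}

#' Normalise FV to the basal (vehicle) death rate
#'
#' By default GRADE analysis uses raw FV values. Cell lines with substantial
#' basal death have vehicle FV well below 1, which compresses the drug FV
#' scale; this opt-in rescaling maps the vehicle FV to 1 (`fv / fv_vehicle`,
#' capped at 1).
#'
#' @param fv Observed FV fraction(s).
#' @param fv_vehicle FV of the vehicle control, in (0, 1\].
#' @return Rescaled FV in \[0, 1\].
#' @examples
#' normalize_fv_basal(0.45, 0.9)
#' @export
normalize_fv_basal <- function(fv, fv_vehicle) {
  stopifnot(is.numeric(fv), is.numeric(fv_vehicle), length(fv_vehicle) == 1L)
  if (fv_vehicle <= 0) {
    rlang::abort("`fv_vehicle` must be positive: cannot normalise to an all-dead control.",
                 class = "druggrade_error_degenerate_control")
  }
  if (fv_vehicle > 1) {
    rlang::abort("`fv_vehicle` must be at most 1.", class = "druggrade_error_domain")
  }
  pmin(fv / fv_vehicle, 1)
}
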