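#' Fit lethal-fraction death kinetics (onset time and rate)
#'
#' Drug-induced killing typically begins only after a drug- and
#' dose-specific lag and then saturates. The lethal fraction over time is
#' modelled as a lagged saturating exponential:
#' \deqn{LF(t) = LF_{max}\,\big(1 - e^{-D_R (t - D_O)}\big) \; (t \ge D_O),
#'       \qquad LF(t) = 0 \; (t < D_O)}
#' with `D_O` the death onset time (hours), `D_R` the death rate (per hour)
#' and `LF_max` the plateau lethal fraction. This is the minimal form that
#' exposes the onset/rate pair used to characterise killing kinetics.
#' Fitting is plain (unweighted) nonlinear least squares from a single
#' deterministic start.
#'
#' @param times Hours (>= 5 points spanning the response).
#' @param lethal_fractions Lethal fraction (1 - FV) at each time, in \[0, 1\].
#' @return A `grade_death_kinetics`: list with `D_O`, `D_R`, `LF_max`,
#'   `rss`, `n`, `flags`. When the maximum lethal fraction is below 0.05 the
#'   `no_death` flag is set and `D_O`/`D_R` are `NA` (kinetics of a
#'   non-lethal response are meaningless).
#' @examples
#' t <- seq(0, 72, by = 4)
#' lf <- 0.8 * (1 - exp(-0.05 * pmax(t - 24, 0)))
#' fit_death_kinetics(t, lf)
#' @export
fit_death_kinetics <- function(times, lethal_fractions) {
  x <- as.numeric(times)
  y <- as.numeric(lethal_fractions)
  if (length(x) != length(y)) {
    rlang::abort("`times` and `lethal_fractions` must have equal length.",
                 class = "druggrade_error_domain")
  }
  if (length(x) < 5) {
    rlang::abort("at least 5 time points are required to fit death kinetics.",
                 class = "druggrade_error_insufficient_data")
  }
  if (any(y < 0) || any(y > 1)) {
    rlang::abort("lethal fractions must lie in [0, 1].", class = "druggrade_error_domain")
  }
  if (max(y) < 0.05) {
    return(structure(list(D_O = NA_real_, D_R = NA_real_, LF_max = max(y),
                          rss = NA_real_, n = length(x), flags = "no_death"),
                     class = "grade_death_kinetics"))
  }
  onset_guess <- x[which(y >= 0.1 * max(y))[1]]
  start <- list(D_O = max(onset_guess, min(x)), D_R = 0.05, LF_max = max(y))
  lower <- c(D_O = 0, D_R = 1e-4, LF_max = 0.01)
  upper <- c(D_O = max(x), D_R = 10, LF_max = 1)
  fit <- tryCatch(
    lm_fit_bounded(function(p) y - p$LF_max * (1 - exp(-p$D_R * pmax(x - p$D_O, 0))),
                   unlist(start), lower, upper, maxiter = 1000,
                   jacobian_fn = function(p) {
                     lag <- pmax(x - p$D_O, 0)
                     e <- exp(-p$D_R * lag)
                     -cbind(D_O = -p$LF_max * p$D_R * e * (x > p$D_O),
                            D_R = p$LF_max * lag * e,
                            LF_max = 1 - e)
                   }),
    error = function(e) {
      rlang::abort(paste0("death-kinetics fit did not converge: ", conditionMessage(e)),
                   class = "druggrade_error_fit")
    }
  )
  params <- fit$par
  structure(list(D_O = unname(params["D_O"]), D_R = unname(params["D_R"]),
                 LF_max = unname(params["LF_max"]),
                 rss = fit$rss, n = length(x),
                 flags = character()),
            class = "grade_death_kinetics")
}

#' @export
print.grade_death_kinetics <- function(x, ...) {
  if ("no_death" %in% x$flags) {
    cat(sprintf("<grade_death_kinetics> no death (max lethal fraction %.3f)\n", x$LF_max))
  } else {
    cat(sprintf("<grade_death_kinetics> onset D_O = %.2f h, rate D_R = %.4f /h, plateau LF_max = %.3f; rss = %.3g\n",
                x$D_O, x$D_R, x$LF_max, x$rss))
  }
  invisible(x)
}
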