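#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least-squares fit of
#' \deqn{y = a + \frac{d - a}{1 + 10^{(x - b)\,c}}}
#' where `x` is log10 dose, `a` the lower asymptote (E_inf), `b` the log10
#' EC50, `c` the Hill coefficient and `d` the upper asymptote. Box bounds
#' are `a` in \[0, 1\] (\[-1, 1\] for the GR variant), `b` in
#' \[min(x) - 2, max(x) + 2\], `c` in \[0.1, 5\], `d` in \[0, 1\]; the start
#' point is (0.5, median(x), 1, 1). Vehicle (dose 0) must be excluded before
#' the log10 transform. When every response exceeds 0.9 the drug is flagged
#' as non-functional (`no_response`): potency metrics from such fits are
#' noise.
#'
#' @param log10_doses Numeric vector of log10 molar doses (vehicle excluded).
#' @param responses Matching RV, FV or GR values.
#' @param variant One of `"rv"`, `"fv"`, `"gr"`; the GR variant widens the
#'   lower bound of `a` to -1.
#' @param no_response_threshold Responses all above this value raise the
#'   `no_response` flag (default 0.9).
#' @return A `grade_4pl` object: list with `a`, `b`, `c`, `d`, `variant`,
#'   `rss`, `n`, `flags` (character vector, possibly empty: `no_response`,
#'   `boundary_hit`, `fit_fallback`), `bounds`, and the fitted data.
#'   Supports [tidy()], [glance()], `predict()` and [ggplot2::autoplot()].
#' @examples
#' x <- seq(-9, -5.5, by = 0.5)
#' y <- 0.1 + (1 - 0.1) / (1 + 10^((x + 6) * 1.5))
#' fit_4pl(x, y, variant = "fv")
#' @export
fit_4pl <- function(log10_doses, responses, variant = c("rv", "fv", "gr"),
                    no_response_threshold = 0.9) {
  variant <- match.arg(variant)
  x <- as.numeric(log10_doses)
  y <- as.numeric(responses)
  if (length(x) != length(y)) {
    rlang::abort("`log10_doses` and `responses` must have equal length.",
                 class = "druggrade_error_domain")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) {
    rlang::abort("at least 4 dose points are required to fit a 4PL curve.",
                 class = "druggrade_error_insufficient_data")
  }
  lower <- c(a = if (variant == "gr") -1 else 0, b = min(x) - 2, c = 0.1, d = 0)
  upper <- c(a = 1, b = max(x) + 2, c = 5, d = 1)
  start <- c(a = 0.5, b = stats::median(x), c = 1, d = 1)

  flags <- character()
  if (all(y > no_response_threshold)) flags <- c(flags, "no_response")

  fit <- tryCatch(
    lm_fit_bounded(function(p) y - fourpl(x, p), start, lower, upper,
                   jacobian_fn = function(p) fourpl_jacobian(x, p)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    if ("no_response" %in% flags) {
      # flat curve: degenerate but representable fit at the asymptote
      params <- c(a = unname(lower["a"]), b = unname(start["b"]), c = 0.1,
                  d = max(min(mean(y), 1), 0))
      flags <- c(flags, "fit_fallback")
      rss <- sum((y - fourpl(x, params))^2)
    } else {
      rlang::abort(paste0("4PL fit did not converge: ", conditionMessage(fit)),
                   class = "druggrade_error_fit")
    }
  } else {
    params <- fit$par
    rss <- fit$rss
  }
  at_bound <- abs(params - lower) < 1e-6 | abs(params - upper) < 1e-6
  if (any(at_bound[c("a", "c", "d")]) || at_bound["b"]) {
    flags <- c(flags, "boundary_hit")
  }
  structure(
    list(a = unname(params["a"]), b = unname(params["b"]),
         c = unname(params["c"]), d = unname(params["d"]),
         variant = variant, rss = rss, n = length(x),
         flags = unique(flags), lower = lower, upper = upper,
         data = tibble::tibble(log10_dose = x, response = y)),
    class = "grade_4pl"
  )
}

fourpl <- function(x, p) {
  p[["a"]] + (p[["d"]] - p[["a"]]) / (1 + 10^((x - p[["b"]]) * p[["c"]]))
}

# Jacobian of the residuals (y - 4PL); the analytic form keeps the bounded
# Levenberg-Marquardt search from stalling where finite differences flatten out
fourpl_jacobian <- function(x, p) {
  s <- 10^((x - p[["b"]]) * p[["c"]])
  den <- 1 + s
  span <- p[["d"]] - p[["a"]]
  -cbind(a = 1 - 1 / den,
         b = span * s * log(10) * p[["c"]] / den^2,
         c = -span * s * log(10) * (x - p[["b"]]) / den^2,
         d = 1 / den)
}

#' @export
predict.grade_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$log10_dose else newdata
  fourpl(x, list(a = object$a, b = object$b, c = object$c, d = object$d))
}

#' @export
print.grade_4pl <- function(x, ...) {
  cat(sprintf("<grade_4pl %s> a = %.4f, b (log10 EC50) = %.4f, c (Hill) = %.4f, d = %.4f; rss = %.3g, n = %d%s\n",
              x$variant, x$a, x$b, x$c, x$d, x$rss, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Dose at which a fitted 4PL curve crosses a response level
#'
#' Solves the fitted curve analytically for `y = level`:
#' \deqn{x = b + \log_{10}\!\big((d - a)/(level - a) - 1\big)/c.}
#' With `level = 0.5` this yields the RV50, FV50 or GR50 depending on the
#' fit variant. The curve must actually cross the level
#' (`a < level < d`); a curve that never reaches it raises an
#' undefined-crossing error, distinct from a fit failure.
#'
#' @param fit A `grade_4pl` object.
#' @param level Response level to solve for (default 0.5).
#' @return The log10 dose of the crossing.
#' @examples
#' x <- seq(-9, -5.5, by = 0.5)
#' y <- 1 / (1 + 10^((x + 6)))
#' half_maximal_dose(fit_4pl(x, y, variant = "rv"))
#' @export
half_maximal_dose <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "grade_4pl"), is.numeric(level), length(level) == 1L)
  if (!(fit$a < level && level < fit$d)) {
    rlang::abort(sprintf("fitted curve (a = %.3f, d = %.3f) never crosses level %.3f.",
                         fit$a, fit$d, level),
                 class = "druggrade_error_no_crossing")
  }
  fit$b + log10((fit$d - fit$a) / (level - fit$a) - 1) / fit$c
}
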