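#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL dose-response fit
#'
#' @param x A `grade_4pl` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `lower`, `upper`,
#'   `at_bound`.
#' @export
tidy.grade_4pl <- function(x, ...) {
  est <- c(a = x$a, b = x$b, c = x$c, d = x$d)
  tibble::tibble(term = names(est), estimate = unname(est),
                 lower = unname(x$lower), upper = unname(x$upper),
                 at_bound = abs(est - x$lower) < 1e-6 | abs(est - x$upper) < 1e-6)
}

#' @rdname tidy.grade_4pl
#' @export
glance.grade_4pl <- function(x, ...) {
  tibble::tibble(variant = x$variant, rss = x$rss, n = x$n,
                 no_response = "no_response" %in% x$flags,
                 boundary_hit = "boundary_hit" %in% x$flags)
}

#' Tidy a growth-curve fit
#'
#' @param x A `grade_growth_fit`.
#' @param ... Unused.
#' @export
tidy.grade_growth_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.grade_growth_fit
#' @export
glance.grade_growth_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, doubling_time_h = 1 / x$b,
                 boundary_hit = "boundary_hit" %in% x$flags)
}

#' Tidy a death-kinetics fit
#'
#' @param x A `grade_death_kinetics`.
#' @param ... Unused.
#' @export
tidy.grade_death_kinetics <- function(x, ...) {
  tibble::tibble(term = c("D_O", "D_R", "LF_max"),
                 estimate = c(x$D_O, x$D_R, x$LF_max))
}

#' @rdname tidy.grade_death_kinetics
#' @export
glance.grade_death_kinetics <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, no_death = "no_death" %in% x$flags)
}

#' Tidy a GRADE result
#'
#' @param x A `grade_result`.
#' @param ... Unused.
#' @return A one-row tibble with the score and its fit diagnostics; GRADE is
#'   reported to one decimal place in printed output but kept at full
#'   precision here.
#' @export
tidy.grade_result <- function(x, ...) {
  tibble::tibble(drug = x$drug %||% NA_character_,
                 cell_line = x$cell_line %||% NA_character_,
                 grade = x$grade, m_drug = x$m_drug, m_max = x$m_max,
                 theta = x$theta, intercept = x$intercept,
                 n_doses_used = x$n_doses_used,
                 flags = paste(x$flags, collapse = ";"))
}

#' @rdname tidy.grade_result
#' @export
glance.grade_result <- function(x, ...) {
  tibble::tibble(grade = x$grade, n_doses_used = x$n_doses_used,
                 clamped = "clamped" %in% x$flags)
}
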