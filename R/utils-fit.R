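# Bounded Levenberg-Marquardt least squares on a residual function.
# Thin wrapper over minpack.lm::nls.lm that returns coefficients and rss;
# avoids nlsLM's post-hoc nlsModel construction, which rejects perfect fits
# (zero residual) with a singular-gradient error.
lm_fit_bounded <- function(residual_fn, start, lower, upper, maxiter = 500,
                           jacobian_fn = NULL) {
  out <- minpack.lm::nls.lm(
    par = as.list(start), lower = lower, upper = upper, fn = residual_fn,
    jac = jacobian_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter)
  )
  if (out$info %in% c(0, 9)) {
    rlang::abort(paste0("nonlinear least squares did not converge: ", out$message),
                 class = "druggrade_error_fit")
  }
  list(par = unlist(out$par), rss = sum(out$fvec^2))
}
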