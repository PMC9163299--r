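#' Confidence intervals for GEE coefficients
#'
#' Wald intervals on the robust (sandwich) standard errors.  With few
#' clusters the normal-quantile interval is anti-conservative, so the
#' default critical value is a Student-t quantile with
#' `n_clusters - n_coefficients` degrees of freedom — the usual
#' small-cluster convention for sandwich-based inference.
#'
#' @param object a [fit_gee()] fit.
#' @param parm coefficients to include (names or indices; default all).
#' @param level confidence level (default 0.95).
#' @param use_t logical; `FALSE` uses the normal quantile.
#' @param ... unused.
#' @return Matrix with columns `lower`, `upper`.
#' @export
confint.gee_fit <- function(object, parm = NULL, level = 0.95,
                            use_t = TRUE, ...) {
  cf <- object$coefficients
  if (is.null(parm)) parm <- seq_along(cf)
  df <- object$n_clusters - length(cf)
  q <- if (use_t && df > 0) stats::qt(1 - (1 - level) / 2, df)
       else stats::qnorm(1 - (1 - level) / 2)
  lo <- cf[parm] - q * object$robust_se[parm]
  hi <- cf[parm] + q * object$robust_se[parm]
  out <- cbind(lower = lo, upper = hi)
  rownames(out) <- names(cf)[parm]
  out
}
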