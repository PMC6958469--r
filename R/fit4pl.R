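#' Four-parameter logistic (variable-slope) dose-response fit
#'
#' Fits the four-parameter logistic model in log10-dose space,
#' \deqn{v(D) = bottom + \frac{top - bottom}{1 + (D/ec_{50})^{hill}},}
#' the "log(inhibitor) vs. response - variable slope" model of standard
#' curve-fitting software. With `hill > 0` viability falls from `top` (zero
#' dose) to `bottom` (infinite dose); the sign of `hill` encodes direction.
#' Least squares via Levenberg-Marquardt ([minpack.lm::nlsLM()]) with
#' multi-start initialization (data-driven, steep, shallow) to avoid local
#' minima. All wells are used (replicates are not averaged).
#'
#' @param curve a [dose_response_curve()].
#' @return An object of class `four_pl_fit`: list with `top`, `bottom`,
#'   `hill`, `ec50`, `absolute_ic50` (see [absolute_ic50()]; `NA` when the
#'   curve never crosses 50% of control), `ic50_status`, `residual_sse`,
#'   `conc_range`, `agent`, `unit`.
#' @examples
#' d <- 10^seq(-1, 2, length.out = 8)
#' cv <- dose_response_curve(d, 1 / (1 + d / 10))
#' fit_4pl(cv)
#' @seealso [absolute_ic50()], [fit_median_effect()]
#' @export
fit_4pl <- function(curve) {
  stopifnot(inherits(curve, "dr_curve"))
  keep <- curve$conc > 0
  x <- log10(curve$conc[keep])
  v <- curve$viability[keep]
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct positive concentrations to fit a 4PL",
         call. = FALSE)
  if (diff(range(v)) < .Machine$double.eps^0.5)
    stop("constant viability curve: nothing to fit", call. = FALSE)

  dat <- data.frame(x = x, v = v)
  model <- v ~ bottom + (top - bottom) / (1 + 10^(hill * (x - le)))

  # data-driven start: ec50 guess at the dose whose mean viability is closest
  # to the half-span of the observed responses
  cm <- curve_means(curve)
  cm <- cm[cm$conc > 0, , drop = FALSE]
  mid <- log10(cm$conc[which.min(abs(cm$viability - mean(range(v))))])
  if (!is.finite(mid)) mid <- stats::median(x)
  starts <- list(
    list(top = max(v), bottom = min(v), hill = 1, le = mid),
    list(top = max(v), bottom = min(v), hill = 3, le = mid),
    list(top = max(v), bottom = min(v), hill = 0.5, le = stats::median(x))
  )

  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(model, data = dat, start = s,
                        lower = c(-0.5, -0.5, -20, min(x) - 3),
                        upper = c(2, 2, 20, max(x) + 3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      sse <- sum(stats::resid(f)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = f, sse = sse)
    }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from all starting points (",
         length(x), " wells, viability range ",
         paste(signif(range(v), 3), collapse = "-"), ")", call. = FALSE)

  p <- as.list(stats::coef(best$fit))
  out <- structure(
    list(top = p$top, bottom = p$bottom, hill = p$hill, ec50 = 10^p$le,
         absolute_ic50 = NA_real_, ic50_status = "undefined",
         residual_sse = best$sse,
         conc_range = range(curve$conc[keep]),
         agent = curve$agent, unit = curve$unit),
    class = "four_pl_fit")
  ic <- absolute_ic50(out)
  out$absolute_ic50 <- as.vector(ic)
  out$ic50_status <- attr(ic, "status")
  out
}

#' Absolute IC50 of a fitted 4PL curve
#'
#' The unique concentration at which predicted viability equals 50% of the
#' untreated control (0.5 on the fraction-of-control scale), inverted in
#' closed form from the 4PL parameters:
#' \deqn{IC_{50} = ec_{50} \left(\frac{top - 0.5}{0.5 - bottom}\right)^{1/hill}.}
#' This is the "absolute" IC50 (relative to control), not the curve midpoint
#' `ec50`, and is undefined when the fitted span does not cross 0.5.
#'
#' @param fit a `four_pl_fit`.
#' @param level effect level on the control scale (default 0.5).
#' @return The concentration, with attribute `status` one of `"ok"`,
#'   `"bottom-above-half"` (plateau never falls to the level),
#'   `"top-below-half"` (curve starts below the level); `NA` unless `"ok"`.
#'   An `extrapolated` attribute flags crossings more than one decade outside
#'   the tested concentration range.
#' @examples
#' f <- structure(list(top = 1, bottom = 0.2, hill = 2, ec50 = 5,
#'                     conc_range = c(0.1, 100)), class = "four_pl_fit")
#' absolute_ic50(f) # 5 * (5/3)^(1/2) = 6.455
#' @export
absolute_ic50 <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "four_pl_fit"))
  top <- fit$top; bottom <- fit$bottom; hill <- fit$hill
  # orient so "hi" is the zero-dose plateau
  hi <- if (hill >= 0) top else bottom
  lo <- if (hill >= 0) bottom else top
  if (hi <= level && lo <= level)
    return(structure(NA_real_, status = "top-below-half"))
  if (lo >= level)
    return(structure(NA_real_, status = "bottom-above-half"))
  ratio <- (top - level) / (level - bottom)
  d <- fit$ec50 * ratio^(1 / hill)
  extrap <- FALSE
  if (!is.null(fit$conc_range)) {
    extrap <- d < fit$conc_range[1] / 10 || d > fit$conc_range[2] * 10
  }
  structure(d, status = "ok", extrapolated = extrap)
}

#' Predict viability from a 4PL fit
#' @param object a `four_pl_fit`.
#' @param conc concentrations at which to predict.
#' @param ... unused.
#' @return Predicted viability fractions.
#' @export
predict.four_pl_fit <- function(object, conc, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (conc / object$ec50)^object$hill)
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("<four_pl_fit> %s: top %.3f bottom %.3f hill %.3f ec50 %.4g %s\n",
              x$agent, x$top, x$bottom, x$hill, x$ec50, x$unit))
  if (identical(x$ic50_status, "ok"))
    cat(sprintf("  absolute IC50: %.4g %s\n", x$absolute_ic50, x$unit))
  else
    cat(sprintf("  absolute IC50: undefined (%s)\n", x$ic50_status))
  invisible(x)
}
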