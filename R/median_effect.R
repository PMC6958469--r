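#' Median-effect (Chou) fit of a dose-response curve
#'
#' Linearizes the median-effect equation \eqn{f_a/f_u = (D/D_m)^m}, where
#' \eqn{f_a = 1 -} viability is the fraction affected (relative to untreated
#' control) and \eqn{f_u = 1 - f_a}, by regressing
#' \eqn{\log_{10}(f_a/f_u)} on \eqn{\log_{10} D}. The slope is the
#' median-effect exponent `m` and the intercept \eqn{-m \log_{10} D_m} gives
#' the median-effect dose `Dm`, the dose producing exactly 50% effect under
#' the fitted model. A noiseless 4PL curve with `bottom = 0`, `top = 1` is an
#' exact median-effect curve with `Dm = ec50` and `m = hill`.
#'
#' Replicates are averaged per concentration before regression, and viability
#' is clipped into an open interval before the log-odds transform (the
#' transform is undefined at 0 and 1).
#'
#' @param curve a [dose_response_curve()].
#' @param clip two-element numeric, the open viability interval retained
#'   before transforming (default `c(0.001, 0.999)`).
#' @return An object of class `median_effect_fit`: list with `dm`, `m`,
#'   `r_squared`, `n_points`, `agent`, `unit`.
#' @examples
#' d <- 10^seq(-1, 2, length.out = 8)
#' fit_median_effect(dose_response_curve(d, 1 / (1 + d / 10)))  # dm 10, m 1
#' @export
fit_median_effect <- function(curve, clip = c(0.001, 0.999)) {
  stopifnot(inherits(curve, "dr_curve"))
  stopifnot(length(clip) == 2L, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
  cm <- curve_means(curve)
  cm <- cm[cm$conc > 0, , drop = FALSE]
  usable <- sum(cm$viability > 0 & cm$viability < 1)
  if (usable < 3L)
    stop("insufficient dynamic range: fewer than 3 concentrations with ",
         "fraction affected strictly inside (0, 1)", call. = FALSE)
  v <- pmin(pmax(cm$viability, clip[1]), clip[2])
  fa <- 1 - v
  y <- log10(fa / (1 - fa))
  fit <- stats::lm(y ~ log10(cm$conc))
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || abs(m) < .Machine$double.eps^0.5)
    stop("median-effect slope is degenerate (flat log-odds curve)",
         call. = FALSE)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 1 else max(0, 1 - sum(stats::resid(fit)^2) / sst)
  structure(
    list(dm = 10^(-b / m), m = m,
         r_squared = r2, n_points = nrow(cm),
         agent = curve$agent, unit = curve$unit),
    class = "median_effect_fit")
}

#' Iso-effective dose from a median-effect fit
#'
#' Dose at which the fitted model yields fraction affected `effect`:
#' \eqn{D = D_m (f_a/f_u)^{1/m}}. At `effect = 0.5` this is `Dm` exactly.
#'
#' @param fit a `median_effect_fit`.
#' @param effect fraction affected, in (0, 1).
#' @return Dose in the curve's concentration unit.
#' @export
me_dose_at <- function(fit, effect = 0.5) {
  stopifnot(inherits(fit, "median_effect_fit"), effect > 0, effect < 1)
  fit$dm * (effect / (1 - effect))^(1 / fit$m)
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> %s: Dm %.4g %s, m %.3f, r2 %.4f (%d pts)\n",
              x$agent, x$dm, x$unit, x$m, x$r_squared, x$n_points))
  invisible(x)
}
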