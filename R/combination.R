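#' Fixed-ratio combination design
#'
#' Describes a fixed-ratio ("constant ratio") combination experiment: each
#' mixture is dosed as a fraction `f` of the two agents' top concentrations,
#' split by a weight pair, so a well at fraction `f` with weights
#' `(wA, wB)` contains `f * wA * top_conc_a` of agent A and
#' `f * wB * top_conc_b` of agent B. The default weights are the nine pairs
#' (0.9, 0.1), (0.8, 0.2), ..., (0.1, 0.9).
#'
#' @param top_conc_a,top_conc_b positive top concentrations of agents A and B
#'   in their native units.
#' @param weights two-column matrix or data.frame of (wA, wB) pairs, each in
#'   (0, 1) with `wA + wB = 1`.
#' @param unit_a,unit_b unit tags.
#' @return An object of class `fixed_ratio_design`.
#' @examples
#' fixed_ratio_design(50, 25, unit_a = "kBq/mL", unit_b = "uM")
#' @export
fixed_ratio_design <- function(top_conc_a, top_conc_b,
                               weights = default_ratio_weights(),
                               unit_a = "conc A", unit_b = "conc B") {
  stopifnot(is.numeric(top_conc_a), top_conc_a > 0,
            is.numeric(top_conc_b), top_conc_b > 0)
  w <- as.matrix(weights)
  if (ncol(w) != 2L) stop("`weights` must have two columns (wA, wB)", call. = FALSE)
  if (any(w <= 0) || any(w >= 1) || any(abs(rowSums(w) - 1) > 1e-8))
    stop("each weight pair must lie in (0, 1) and sum to 1", call. = FALSE)
  structure(list(top_conc_a = top_conc_a, top_conc_b = top_conc_b,
                 weights = unname(w), unit_a = unit_a, unit_b = unit_b),
            class = "fixed_ratio_design")
}

#' Default nine fixed-ratio weight pairs
#' @return A 9 x 2 matrix of (wA, wB) pairs (0.9, 0.1) through (0.1, 0.9).
#' @export
default_ratio_weights <- function() {
  wa <- seq(0.9, 0.1, by = -0.1)
  unname(cbind(wa, 1 - wa))
}

#' Combination index (median-effect model) for a fixed-ratio design
#'
#' Chou-Talalay combination-index analysis at a fixed effect level. For each
#' mixture ratio the mixture's own dose-response (on the fraction-of-top
#' axis) is fitted and the combined dose (fraction `f`) reaching the effect
#' level is read off the fit, then decomposed into component doses
#' `d_a = f * wA * top_conc_a`, `d_b = f * wB * top_conc_b`, and
#' \deqn{CI = d_a / D_A + d_b / D_B,}
#' where `D_A`, `D_B` are the single agents' iso-effective doses from their
#' median-effect fits (`Dm` at the default 50% effect). The mixture crossing
#' is read from a variable-slope 4PL fit of the mixture curve (with a
#' median-effect fit as fallback): the 4PL reproduces a median-effect curve
#' exactly and tracks mixture surfaces that deviate from the median-effect
#' shape, so the decomposed doses reflect the observed 50% crossing rather
#' than a globally linearized one. CI < 1 indicates
#' Loewe synergy; the classification thresholds used here are CI < 0.8
#' synergistic, 0.8-1.2 additive (boundaries inclusive), CI > 1.2
#' antagonistic. The average CI is the arithmetic mean over evaluable ratios.
#'
#' Mixture curves that never reach the effect level (maximum observed
#' fraction affected below it) are flagged and excluded from the average; the
#' result carries the count.
#'
#' @param design a [fixed_ratio_design()].
#' @param fit_a,fit_b single-agent [fit_median_effect()] fits (units must
#'   match the design's top concentrations).
#' @param mixture_curves list of [dose_response_curve()]s, one per weight
#'   pair in design order, with `conc` on the fraction-of-top axis.
#' @param effect effect level (fraction affected); 0.5 by default, the level
#'   the IC50 isobologram is drawn at.
#' @return An object of class `ci_result`: list with `per_ratio` (data.frame:
#'   `w_a`, `w_b`, `f_effect`, `dose_a`, `dose_b`, `ci`, `evaluable`),
#'   `average_ci`, `classification`, `n_excluded`, `effect`.
#' @export
combination_index <- function(design, fit_a, fit_b, mixture_curves,
                              effect = 0.5) {
  stopifnot(inherits(design, "fixed_ratio_design"),
            inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"))
  n <- nrow(design$weights)
  if (length(mixture_curves) != n)
    stop("need one mixture curve per weight pair (", n, ")", call. = FALSE)
  d50_a <- me_dose_at(fit_a, effect)
  d50_b <- me_dose_at(fit_b, effect)

  rows <- lapply(seq_len(n), function(i) {
    w <- design$weights[i, ]
    curve <- mixture_curves[[i]]
    stopifnot(inherits(curve, "dr_curve"))
    cm <- curve_means(curve)
    reached <- max(1 - cm$viability) >= effect
    f <- NA_real_; ci <- NA_real_; da <- NA_real_; db <- NA_real_
    if (reached) {
      f <- mixture_f_at(curve, effect)
      if (is.finite(f)) {
        da <- f * w[1] * design$top_conc_a
        db <- f * w[2] * design$top_conc_b
        ci <- da / d50_a + db / d50_b
      } else reached <- FALSE
    }
    data.frame(w_a = w[1], w_b = w[2], f_effect = f,
               dose_a = da, dose_b = db, ci = ci, evaluable = reached)
  })
  per_ratio <- do.call(rbind, rows)
  n_excl <- sum(!per_ratio$evaluable)
  if (n_excl > 0L)
    warning(n_excl, " mixture ratio(s) did not reach the ", effect,
            " effect level and were excluded from the average CI",
            call. = FALSE)
  if (all(!per_ratio$evaluable))
    stop("no mixture ratio reached the requested effect level", call. = FALSE)
  avg <- mean(per_ratio$ci[per_ratio$evaluable])
  structure(
    list(per_ratio = per_ratio, average_ci = avg,
         classification = classify_ci(avg), n_excluded = n_excl,
         effect = effect, d50_a = d50_a, d50_b = d50_b,
         unit_a = design$unit_a, unit_b = design$unit_b),
    class = "ci_result")
}

#' Classify a combination index
#'
#' CI < 0.8 synergistic; 0.8 <= CI <= 1.2 additive; CI > 1.2 antagonistic.
#' The thresholds partition the CI line with no gaps; boundary values fall in
#' the additive class.
#'
#' @param ci numeric combination index (vectorized).
#' @return Character vector in `{"synergistic", "additive", "antagonistic"}`.
#' @export
classify_ci <- function(ci) {
  stopifnot(is.numeric(ci), all(is.finite(ci)), all(ci >= 0))
  ifelse(ci < 0.8, "synergistic", ifelse(ci > 1.2, "antagonistic", "additive"))
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("<ci_result> %d/%d evaluable ratios at effect %.2f\n",
              sum(x$per_ratio$evaluable), nrow(x$per_ratio), x$effect))
  cat(sprintf("  average CI %.3f -> %s\n", x$average_ci, x$classification))
  invisible(x)
}

#' Isobologram coordinates at a fixed effect level
#'
#' Returns the two single-agent axis intercepts (the iso-effective doses,
#' absolute IC50s at the default 50% level) plus one (dose A, dose B) point
#' per evaluable mixture ratio. Points below the straight additivity line
#' joining the intercepts correspond to CI < 1.
#'
#' @param fit_a,fit_b single-agent fits: either `four_pl_fit` (uses the
#'   absolute IC50) or `median_effect_fit` (uses the iso-effective dose).
#' @param ci_result a [combination_index()] result.
#' @return data.frame with columns `dose_a`, `dose_b`, `effect_level`,
#'   `point` (`"intercept_a"`, `"intercept_b"`, or `"mixture"`).
#' @export
isobologram_points <- function(fit_a, fit_b, ci_result) {
  stopifnot(inherits(ci_result, "ci_result"))
  ia <- iso_dose(fit_a, ci_result$effect)
  ib <- iso_dose(fit_b, ci_result$effect)
  pr <- ci_result$per_ratio
  pr <- pr[pr$evaluable, , drop = FALSE]
  rbind(
    data.frame(dose_a = ia, dose_b = 0, effect_level = ci_result$effect,
               point = "intercept_a"),
    data.frame(dose_a = 0, dose_b = ib, effect_level = ci_result$effect,
               point = "intercept_b"),
    data.frame(dose_a = pr$dose_a, dose_b = pr$dose_b,
               effect_level = ci_result$effect, point = "mixture")
  )
}

# combined-dose fraction at which a mixture curve crosses the effect level:
# 4PL crossing first, median-effect fallback
mixture_f_at <- function(curve, effect) {
  f4 <- tryCatch(fit_4pl(curve), error = function(e) NULL)
  if (!is.null(f4)) {
    d <- absolute_ic50(f4, level = 1 - effect)
    if (identical(attr(d, "status"), "ok")) return(as.numeric(d))
  }
  fme <- tryCatch(fit_median_effect(curve), error = function(e) NULL)
  if (!is.null(fme) && fme$m > 0) return(me_dose_at(fme, effect))
  NA_real_
}

# iso-effective single-agent dose from either fit class
iso_dose <- function(fit, effect) {
  if (inherits(fit, "median_effect_fit")) return(me_dose_at(fit, effect))
  if (inherits(fit, "four_pl_fit")) {
    d <- absolute_ic50(fit, level = 1 - effect)
    if (!identical(attr(d, "status"), "ok"))
      stop("single-agent IC50 undefined (", attr(d, "status"), ")",
           call. = FALSE)
    return(as.numeric(d))
  }
  stop("`fit` must be a four_pl_fit or median_effect_fit", call. = FALSE)
}
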