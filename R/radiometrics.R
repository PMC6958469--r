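#' Radionuclide parameters
#'
#' A nuclide is described by its physical half-life; the decay constant is
#' `lambda = ln(2) / half-life`. Times are handled internally in hours.
#'
#' @param name nuclide label, e.g. `"Th-227"`.
#' @param half_life positive half-life value.
#' @param unit unit of `half_life`: `"days"`, `"hours"`, or `"seconds"`.
#' @return Object of class `nuclide` with fields `name`, `half_life_h`.
#' @examples
#' nuclide("Th-227", 18.7, "days")
#' @export
nuclide <- function(name, half_life, unit = c("days", "hours", "seconds")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(half_life), length(half_life) == 1L, half_life > 0)
  hl_h <- switch(unit, days = half_life * 24, hours = half_life,
                 seconds = half_life / 3600)
  structure(list(name = as.character(name)[1L], half_life_h = hl_h),
            class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: half-life %.4g d\n", x$name, x$half_life_h / 24))
  invisible(x)
}

#' Built-in nuclide registry
#'
#' Th-227 at 18.7 days (as used throughout the analysis) and its decay
#' daughter Ra-223 at 11.43 days (standard nuclide data). Individual entries
#' can be overridden by passing replacement [nuclide()] objects.
#'
#' @param ... named [nuclide()] overrides or additions, e.g.
#'   `"Ra-223" = nuclide("Ra-223", 11.4354, "days")`.
#' @return Named list of `nuclide` objects.
#' @export
nuclide_registry <- function(...) {
  reg <- list("Th-227" = nuclide("Th-227", 18.7, "days"),
              "Ra-223" = nuclide("Ra-223", 11.43, "days"))
  over <- list(...)
  for (nm in names(over)) {
    stopifnot(inherits(over[[nm]], "nuclide"))
    reg[[nm]] <- over[[nm]]
  }
  reg
}

# decay constant per hour
lambda_h <- function(nuc) {
  stopifnot(inherits(nuc, "nuclide"))
  log(2) / nuc$half_life_h
}

#' Forward radioactive decay
#'
#' Activity remaining after `elapsed_h` hours: `A * 2^(-elapsed/half-life)`.
#'
#' @param activity activity at time zero (any activity unit).
#' @param elapsed_h elapsed time in hours, non-negative.
#' @param nuc a [nuclide()].
#' @return Activity at `elapsed_h`.
#' @export
forward_decay <- function(activity, elapsed_h, nuc) {
  check_elapsed(elapsed_h)
  activity * 2^(-elapsed_h / nuc$half_life_h)
}

#' Decay-correct a measured activity back to a reference time
#'
#' Inverse of [forward_decay()]: a count measured `elapsed_h` hours after
#' injection is corrected to injection time by `A * 2^(elapsed/half-life)`.
#'
#' @inheritParams forward_decay
#' @param activity measured activity at `elapsed_h`.
#' @return Activity at the reference (injection) time.
#' @examples
#' th <- nuclide("Th-227", 18.7, "days")
#' decay_correct(1, 336, th)  # 2^(14/18.7) = 1.680
#' @export
decay_correct <- function(activity, elapsed_h, nuc) {
  check_elapsed(elapsed_h)
  activity * 2^(elapsed_h / nuc$half_life_h)
}

check_elapsed <- function(elapsed_h) {
  if (any(!is.finite(elapsed_h)) || any(elapsed_h < 0))
    stop("elapsed time must be finite and non-negative", call. = FALSE)
}

#' Percent injected activity per gram of tissue
#'
#' Decay-corrects the measured sample activity to injection time, divides by
#' the injected activity and the sample mass, and expresses the result in
#' percent: `100 * decay_correct(A, t) / (A_injected * mass)`.
#'
#' @param activity_bq measured sample activity (Bq) at `time_h`.
#' @param time_h harvest time, hours post-injection.
#' @param mass_g sample mass in grams (> 0).
#' @param injected_bq injected activity (Bq) at injection time (> 0).
#' @param nuc a [nuclide()] (the counted nuclide).
#' @return %IA/g (vectorized).
#' @export
percent_ia_per_gram <- function(activity_bq, time_h, mass_g, injected_bq, nuc) {
  stopifnot(all(is.finite(activity_bq)), all(activity_bq >= 0))
  if (any(!is.finite(mass_g)) || any(mass_g <= 0))
    stop("sample mass must be positive", call. = FALSE)
  if (any(!is.finite(injected_bq)) || any(injected_bq <= 0))
    stop("injected activity must be positive", call. = FALSE)
  100 * decay_correct(activity_bq, time_h, nuc) / (injected_bq * mass_g)
}

#' Summarize a biodistribution table as %IA/g per organ and time
#'
#' @param biodist data.frame with columns `organ`, `time_h`, `activity_bq`,
#'   `mass_g`, `injected_bq` (one row per sample).
#' @param nuc a [nuclide()].
#' @return data.frame with `organ`, `time_h`, `mean_pct_ia_g`, `sd_pct_ia_g`,
#'   `n`.
#' @export
biodist_summary <- function(biodist, nuc) {
  req <- c("organ", "time_h", "activity_bq", "mass_g", "injected_bq")
  miss <- setdiff(req, names(biodist))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  pct <- percent_ia_per_gram(biodist$activity_bq, biodist$time_h,
                             biodist$mass_g, biodist$injected_bq, nuc)
  agg <- stats::aggregate(pct,
                          by = list(organ = biodist$organ,
                                    time_h = biodist$time_h),
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  data.frame(organ = agg$organ, time_h = agg$time_h,
             mean_pct_ia_g = agg$x[, "mean"], sd_pct_ia_g = agg$x[, "sd"],
             n = as.integer(agg$x[, "n"]))
}

#' Tumor-to-blood activity ratio at a harvest time
#'
#' @param summary a [biodist_summary()] data.frame (or any table with
#'   `organ`, `time_h`, `mean_pct_ia_g`).
#' @param time_h requested harvest time.
#' @param tumor,blood organ labels.
#' @return list with `ratio` (`NA` when blood activity is zero) and `status`.
#' @export
tumor_to_blood <- function(summary, time_h, tumor = "tumor", blood = "blood") {
  tv <- summary$mean_pct_ia_g[summary$organ == tumor & summary$time_h == time_h]
  bv <- summary$mean_pct_ia_g[summary$organ == blood & summary$time_h == time_h]
  if (length(tv) != 1L || length(bv) != 1L)
    stop("need exactly one tumor and one blood entry at time ", time_h,
         call. = FALSE)
  if (bv <= 0) return(list(ratio = NA_real_, status = "blood activity zero"))
  list(ratio = tv / bv, status = "ok")
}

#' Specific activity of a radiolabeled protein dose
#'
#' Activity dose divided by protein dose, converted to kBq per microgram:
#' e.g. 300 kBq/kg at a 0.14 mg/kg antibody dose is 2.14 kBq/ug.
#'
#' @param activity_kbq_per_kg activity dose in kBq per kg body weight.
#' @param protein_mg_per_kg protein dose in mg per kg body weight (> 0).
#' @return Specific activity in kBq/ug.
#' @export
specific_activity <- function(activity_kbq_per_kg, protein_mg_per_kg) {
  if (any(!is.finite(protein_mg_per_kg)) || any(protein_mg_per_kg <= 0))
    stop("protein dose must be positive", call. = FALSE)
  stopifnot(all(is.finite(activity_kbq_per_kg)), all(activity_kbq_per_kg >= 0))
  activity_kbq_per_kg / protein_mg_per_kg / 1000
}

#' Convert an activity concentration to molar concentration
#'
#' The number of atoms sustaining activity `A` is `N = A / lambda`; dividing
#' by Avogadro's number gives moles. For Th-227 (18.7 d) one Bq corresponds
#' to about 2.33e6 atoms, so 22 kBq/mL is about 85 pM.
#'
#' @param bq_per_l activity concentration in Bq per litre.
#' @param nuc a [nuclide()].
#' @return Molar concentration (mol/L), vectorized.
#' @export
activity_to_molar <- function(bq_per_l, nuc) {
  stopifnot(all(is.finite(bq_per_l)), all(bq_per_l >= 0))
  lam_s <- lambda_h(nuc) / 3600
  bq_per_l / lam_s / 6.02214076e23
}

#' @rdname activity_to_molar
#' @param kbq_per_ml activity concentration in kBq per mL.
#' @return `kbq_per_ml_to_pm()`: picomolar concentration.
#' @export
kbq_per_ml_to_pm <- function(kbq_per_ml, nuc) {
  activity_to_molar(kbq_per_ml * 1e6, nuc) * 1e12
}

#' Bateman ingrowth of a radioactive daughter
#'
#' Activity of a daughter nuclide growing in from a pure parent source
#' (daughter absent at time zero):
#' \deqn{A_d(t) = A_p(0) \frac{\lambda_d}{\lambda_d - \lambda_p}
#'       (e^{-\lambda_p t} - e^{-\lambda_d t}).}
#' For Th-227 -> Ra-223 the daughter/parent activity ratio rises
#' monotonically toward the transient-equilibrium value
#' `lambda_d / (lambda_d - lambda_p)` (about 2.57) and the daughter activity
#' peaks at `ln(lambda_d/lambda_p) / (lambda_d - lambda_p)` (about 20.9 d).
#' Equal decay constants are handled by the limiting form
#' `A_p(0) * lambda * t * exp(-lambda * t)`.
#'
#' @param parent_bq_t0 parent activity at time zero (Bq).
#' @param elapsed_h elapsed time in hours (vectorized), non-negative.
#' @param parent,daughter [nuclide()] objects.
#' @return Daughter activity (Bq) at `elapsed_h`.
#' @export
bateman_ingrowth <- function(parent_bq_t0, elapsed_h, parent, daughter) {
  check_elapsed(elapsed_h)
  lp <- lambda_h(parent); ld <- lambda_h(daughter)
  if (abs(ld - lp) < 1e-9 * lp) {
    lam <- (lp + ld) / 2
    return(parent_bq_t0 * lam * elapsed_h * exp(-lam * elapsed_h))
  }
  parent_bq_t0 * ld / (ld - lp) *
    (exp(-lp * elapsed_h) - exp(-ld * elapsed_h))
}
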