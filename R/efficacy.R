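#' Xenograft efficacy study container
#'
#' Wraps per-animal tumor-volume time series grouped by treatment arm and
#' applies humane-endpoint censoring: each animal is censored at its first
#' measurement at or above the endpoint volume (that triggering measurement
#' is retained; later measurements are excluded from group summaries). No
#' last-observation-carried-forward is applied.
#'
#' @param measurements data.frame with columns `animal_id`, `group`, `day`,
#'   `volume_mm3` and optionally `body_weight_g`.
#' @param vehicle_group label of the vehicle/control arm.
#' @param endpoint_mm3 humane-endpoint tumor volume (default 1500 mm3).
#' @return An object of class `efficacy_study`: list with `data` (with a
#'   logical `censored` column marking excluded rows), `censoring`
#'   (data.frame: `animal_id`, `day`, `reason`), `vehicle_group`,
#'   `endpoint_mm3`, `groups`.
#' @export
efficacy_study <- function(measurements, vehicle_group = "vehicle",
                           endpoint_mm3 = 1500) {
  req <- c("animal_id", "group", "day", "volume_mm3")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- measurements[order(measurements$animal_id, measurements$day), ]
  if (any(!is.finite(d$volume_mm3)) || any(d$volume_mm3 < 0))
    stop("tumor volumes must be finite and non-negative", call. = FALSE)
  grp_per_animal <- tapply(as.character(d$group), d$animal_id,
                           function(g) length(unique(g)))
  if (any(grp_per_animal > 1L))
    stop("each animal must belong to exactly one group", call. = FALSE)
  if (!vehicle_group %in% d$group)
    stop("vehicle group '", vehicle_group, "' not present", call. = FALSE)

  d$censored <- FALSE
  cens <- list()
  for (a in unique(d$animal_id)) {
    idx <- which(d$animal_id == a)
    hit <- which(d$volume_mm3[idx] >= endpoint_mm3)
    if (length(hit)) {
      first <- hit[1L]
      if (first < length(idx)) d$censored[idx[(first + 1L):length(idx)]] <- TRUE
      cens[[length(cens) + 1L]] <- data.frame(
        animal_id = a, day = d$day[idx[first]],
        reason = sprintf("tumor volume >= %g mm3", endpoint_mm3))
    }
  }
  structure(
    list(data = d,
         censoring = if (length(cens)) do.call(rbind, cens)
                     else data.frame(animal_id = character(), day = numeric(),
                                     reason = character()),
         vehicle_group = vehicle_group, endpoint_mm3 = endpoint_mm3,
         groups = unique(as.character(d$group))),
    class = "efficacy_study")
}

#' @export
print.efficacy_study <- function(x, ...) {
  cat(sprintf("<efficacy_study> %d groups, %d animals, %d censored\n",
              length(x$groups), length(unique(x$data$animal_id)),
              nrow(x$censoring)))
  invisible(x)
}

# uncensored measurements of a group at a day
group_volumes <- function(study, group, day) {
  d <- study$data
  d$volume_mm3[d$group == group & d$day == day & !d$censored]
}

#' Default reference day for treatment-over-control ratios
#'
#' The last study day on which every vehicle animal is still uncensored,
#' so the control mean is not survivorship-biased.
#'
#' @param study an [efficacy_study()].
#' @return A study day.
#' @export
default_reference_day <- function(study) {
  stopifnot(inherits(study, "efficacy_study"))
  d <- study$data[study$data$group == study$vehicle_group, ]
  n_animals <- length(unique(d$animal_id))
  days <- sort(unique(d$day))
  ok <- vapply(days, function(dy)
    sum(d$day == dy & !d$censored) == n_animals, logical(1))
  if (!any(ok))
    stop("no day with all vehicle animals uncensored", call. = FALSE)
  max(days[ok])
}

#' Tumor doubling time by log-linear regression
#'
#' Regresses `ln(volume)` on study day; the doubling time is
#' `ln(2) / slope`. For an [efficacy_study()] the group value is the mean
#' over that group's animals (animals with non-positive growth slope are
#' reported as no-growth and excluded from the mean).
#'
#' @param x numeric volume vector, or an [efficacy_study()].
#' @param ... passed to methods.
#' @return For the numeric method, a list `days` (NA when no growth) and
#'   `status` (`"ok"` / `"no growth"`). For the study method, a list with
#'   `per_animal`, mean `days`, and `n_no_growth`.
#' @examples
#' t <- seq(0, 21, by = 3.5)
#' doubling_time(90 * 2^(t / 7.3), day = t)$days  # 7.3
#' @export
doubling_time <- function(x, ...) UseMethod("doubling_time")

#' @rdname doubling_time
#' @param day study days matching the volume vector.
#' @export
doubling_time.numeric <- function(x, day, ...) {
  keep <- is.finite(x) & x > 0
  if (sum(keep) < 3L)
    stop("need at least 3 time points with positive volume", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(log(x[keep]) ~ day[keep]))[2])
  if (!is.finite(slope) || slope <= 0)
    return(list(days = NA_real_, status = "no growth"))
  list(days = log(2) / slope, status = "ok")
}

#' @rdname doubling_time
#' @param group group label (study method).
#' @export
doubling_time.efficacy_study <- function(x, group, ...) {
  d <- x$data[x$data$group == group & !x$data$censored, ]
  if (!nrow(d)) stop("no data for group '", group, "'", call. = FALSE)
  per <- vapply(split(d, d$animal_id), function(dd) {
    if (nrow(dd) < 3L) return(NA_real_)
    doubling_time(dd$volume_mm3, day = dd$day)$days
  }, numeric(1))
  list(per_animal = per, days = mean(per, na.rm = TRUE),
       n_no_growth = sum(is.na(per)))
}

#' Treatment-over-control ratio at a reference day
#'
#' `T/C = mean(treated volumes) / mean(vehicle volumes)` over uncensored
#' animals at the reference day, with the Tukey-adjusted p-value of the
#' group-vs-vehicle contrast from [anova_tukey()] attached.
#'
#' @param study an [efficacy_study()].
#' @param group treatment-arm label.
#' @param reference_day study day; defaults to [default_reference_day()].
#' @param alpha significance level (default 0.05).
#' @return A list of class `tc_result`: `group`, `reference_day`, `t_over_c`,
#'   `p_value` (NA when the ANOVA is not estimable), `significant`, `n_treated`,
#'   `n_vehicle`.
#' @export
tc_ratio <- function(study, group, reference_day = NULL, alpha = 0.05) {
  stopifnot(inherits(study, "efficacy_study"))
  if (is.null(reference_day)) reference_day <- default_reference_day(study)
  tv <- group_volumes(study, group, reference_day)
  vv <- group_volumes(study, study$vehicle_group, reference_day)
  if (!length(vv))
    stop("no uncensored vehicle animal at day ", reference_day,
         "; choose an earlier reference day", call. = FALSE)
  if (!length(tv))
    stop("no uncensored animal in group '", group, "' at day ",
         reference_day, call. = FALSE)
  if (mean(vv) <= 0) stop("vehicle mean volume is zero", call. = FALSE)
  p <- tryCatch({
    at <- anova_tukey(study, reference_day)
    at$p_adj[at$group == group]
  }, error = function(e) NA_real_)
  if (!length(p)) p <- NA_real_
  structure(
    list(group = group, reference_day = reference_day,
         t_over_c = mean(tv) / mean(vv), p_value = p,
         significant = isTRUE(p < alpha),
         n_treated = length(tv), n_vehicle = length(vv)),
    class = "tc_result")
}

#' @export
print.tc_result <- function(x, ...) {
  cat(sprintf("<tc_result> %s day %g: T/C = %.3f (p = %s)\n", x$group,
              x$reference_day, x$t_over_c,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value)))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD versus vehicle
#'
#' One-way ANOVA across all groups on reference-day tumor volumes of
#' uncensored animals, followed by Tukey's honest-significant-difference
#' test; returns the adjusted p-values of each treatment group against the
#' vehicle arm.
#'
#' @param study an [efficacy_study()].
#' @param reference_day study day.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `group`, `diff`, `p_adj`, `significant`.
#' @export
anova_tukey <- function(study, reference_day = NULL, alpha = 0.05) {
  stopifnot(inherits(study, "efficacy_study"))
  if (is.null(reference_day)) reference_day <- default_reference_day(study)
  d <- study$data[study$data$day == reference_day & !study$data$censored, ]
  counts <- table(d$group)
  counts <- counts[counts > 0]
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 animals each at day ", reference_day,
         call. = FALSE)
  d$group <- factor(as.character(d$group))
  fit <- stats::aov(volume_mm3 ~ group, data = d)
  if (sum(stats::resid(fit)^2) < .Machine$double.eps * sum(d$volume_mm3^2 + 1))
    stop("degenerate data: zero within-group variance everywhere",
         call. = FALSE)
  tk <- stats::TukeyHSD(fit)$group
  cmp <- rownames(tk)
  veh <- study$vehicle_group
  sel <- startsWith(cmp, paste0(veh, "-")) | endsWith(cmp, paste0("-", veh))
  other <- cmp[sel]
  other <- ifelse(startsWith(other, paste0(veh, "-")),
                  substring(other, nchar(veh) + 2L),
                  substring(other, 1L, nchar(other) - nchar(veh) - 1L))
  out <- data.frame(group = other, diff = unname(tk[sel, "diff"]),
                    p_adj = unname(tk[sel, "p adj"]))
  out$significant <- out$p_adj < alpha
  out[order(out$group), , drop = FALSE]
}
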