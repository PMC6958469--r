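#' Nadir of a hematology time series
#'
#' Minimum of a cell-count series expressed as a fraction of the baseline
#' (first-day) count, with the day it occurs. A series that never falls
#' below baseline is flagged `"no suppression"` and reported as fraction 1.0
#' at the baseline day.
#'
#' @param day numeric vector of sampling days (baseline first).
#' @param count positive cell counts, same length.
#' @return list with `day`, `fraction`, `baseline`, `status`
#'   (`"ok"` or `"no suppression"`).
#' @examples
#' hematology_nadir(c(0, 12, 26), c(100, 50, 80))  # day 12, fraction 0.5
#' @export
hematology_nadir <- function(day, count) {
  stopifnot(length(day) == length(count), length(day) >= 1L,
            all(is.finite(day)), all(is.finite(count)), all(count > 0))
  ord <- order(day)
  day <- day[ord]; count <- count[ord]
  baseline <- count[1L]
  i <- which.min(count)
  frac <- count[i] / baseline
  if (frac >= 1)
    return(list(day = day[1L], fraction = 1.0, baseline = baseline,
                status = "no suppression"))
  list(day = day[i], fraction = frac, baseline = baseline, status = "ok")
}

#' Recovery day of a hematology time series
#'
#' First post-nadir day on which the count is back to at least
#' `(1 - tolerance)` of baseline; `NA` if never reached.
#'
#' @inheritParams hematology_nadir
#' @param tolerance allowed shortfall from baseline (default 0.1, i.e.
#'   recovery means >= 90% of baseline).
#' @return list with `day` (`NA` when the series never recovers), `status`
#'   (`"ok"`, `"no recovery"`, or `"no suppression"`).
#' @examples
#' hematology_recovery(c(0, 12, 26), c(100, 50, 95))$day  # 26
#' @export
hematology_recovery <- function(day, count, tolerance = 0.1) {
  stopifnot(is.numeric(tolerance), tolerance > 0, tolerance < 1)
  nad <- hematology_nadir(day, count)
  if (nad$status == "no suppression")
    return(list(day = day[order(day)][1L], status = "no suppression"))
  ord <- order(day)
  day <- day[ord]; count <- count[ord]
  post <- day > nad$day & count >= (1 - tolerance) * nad$baseline
  if (!any(post)) return(list(day = NA_real_, status = "no recovery"))
  list(day = min(day[post]), status = "ok")
}

#' Per-group hematology nadir/recovery summary
#'
#' Averages counts per group and day for each lineage column, then reports
#' nadir day, nadir depth (fraction of baseline) and recovery day.
#'
#' @param hema data.frame with columns `animal_id`, `group`, `day` and one
#'   or more lineage count columns.
#' @param lineages character vector of lineage column names (defaults to the
#'   standard three).
#' @param tolerance recovery tolerance (see [hematology_recovery()]).
#' @return data.frame with `group`, `lineage`, `nadir_day`, `nadir_fraction`,
#'   `recovery_day`, `status`.
#' @export
hematology_summary <- function(hema,
                               lineages = c("platelets_1e9_per_l",
                                            "wbc_1e9_per_l",
                                            "rbc_1e12_per_l"),
                               tolerance = 0.1) {
  stopifnot(all(c("group", "day") %in% names(hema)))
  lineages <- intersect(lineages, names(hema))
  if (!length(lineages)) stop("no lineage columns found", call. = FALSE)
  out <- list()
  for (g in unique(as.character(hema$group))) {
    dg <- hema[hema$group == g, ]
    for (lin in lineages) {
      m <- tapply(dg[[lin]], dg$day, mean)
      day <- as.numeric(names(m)); cnt <- as.numeric(m)
      nad <- hematology_nadir(day, cnt)
      rec <- hematology_recovery(day, cnt, tolerance)
      out[[length(out) + 1L]] <- data.frame(
        group = g, lineage = lin, nadir_day = nad$day,
        nadir_fraction = nad$fraction, recovery_day = rec$day,
        status = nad$status)
    }
  }
  do.call(rbind, out)
}
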