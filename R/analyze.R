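#' Split a plates table into dose-response curves and a design
#'
#' Normalizes raw signals against the table's control and blank wells and
#' partitions the wells into the agent-A titration, the agent-B titration,
#' and one mixture curve per fixed-ratio weight. Mixture concentrations are
#' mapped to the dimensionless fraction-of-top axis
#' `f = agent_a_conc / (wA * top_conc_a)`, which avoids mixing the two
#' agents' native units on one dose axis.
#'
#' @param plates data.frame in the `plates.csv` schema (see
#'   [validate_csv()]): `well`, `agent_a_conc`, `agent_b_conc`,
#'   `mixture_weight_a`, `raw_signal`, `is_control`, `is_blank`.
#' @param top_conc_a,top_conc_b top concentrations of the two titrations;
#'   when `NULL`, the maximum single-agent concentration present.
#' @param unit_a,unit_b unit tags for reporting.
#' @return list with `curve_a`, `curve_b` ([dose_response_curve()]s),
#'   `mixtures` (list of curves on the fraction-of-top axis, in decreasing
#'   `w_a` order), and `design` ([fixed_ratio_design()]).
#' @export
plate_curves <- function(plates, top_conc_a = NULL, top_conc_b = NULL,
                         unit_a = "kBq/mL", unit_b = "uM") {
  req <- c("agent_a_conc", "agent_b_conc", "mixture_weight_a", "raw_signal",
           "is_control", "is_blank")
  miss <- setdiff(req, names(plates))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ctrl <- plates$raw_signal[as.logical(plates$is_control)]
  blank <- plates$raw_signal[as.logical(plates$is_blank)]
  if (!length(ctrl) || !length(blank))
    stop("plates table needs control and blank wells", call. = FALSE)
  treated <- plates[!as.logical(plates$is_control) &
                      !as.logical(plates$is_blank), , drop = FALSE]
  treated$viability <- normalize_viability(treated$raw_signal, ctrl, blank)

  is_mix <- !is.na(treated$mixture_weight_a)
  a_only <- !is_mix & treated$agent_a_conc > 0 & treated$agent_b_conc == 0
  b_only <- !is_mix & treated$agent_b_conc > 0 & treated$agent_a_conc == 0
  if (!any(a_only) || !any(b_only))
    stop("plates table needs single-agent titrations for both agents",
         call. = FALSE)
  if (is.null(top_conc_a)) top_conc_a <- max(treated$agent_a_conc[a_only])
  if (is.null(top_conc_b)) top_conc_b <- max(treated$agent_b_conc[b_only])

  curve_a <- dose_response_curve(treated$agent_a_conc[a_only],
                                 treated$viability[a_only],
                                 agent = "agent A", unit = unit_a)
  curve_b <- dose_response_curve(treated$agent_b_conc[b_only],
                                 treated$viability[b_only],
                                 agent = "agent B", unit = unit_b)

  ws <- sort(unique(round(treated$mixture_weight_a[is_mix], 8)),
             decreasing = TRUE)
  mixtures <- lapply(ws, function(w) {
    rows <- is_mix & abs(treated$mixture_weight_a - w) < 1e-8
    f <- treated$agent_a_conc[rows] / (w * top_conc_a)
    dose_response_curve(f, treated$viability[rows],
                        agent = sprintf("mixture wA=%.2f", w),
                        unit = "fraction of top")
  })
  design <- fixed_ratio_design(top_conc_a, top_conc_b,
                               weights = cbind(ws, 1 - ws),
                               unit_a = unit_a, unit_b = unit_b)
  list(curve_a = curve_a, curve_b = curve_b, mixtures = mixtures,
       design = design)
}

#' Full in vitro combination analysis of a plates table
#'
#' Runs the complete in vitro stage: normalization, single-agent 4PL fits
#' with absolute IC50s, single-agent median-effect fits, per-ratio and
#' average combination index, classification, and isobologram coordinates.
#'
#' @inheritParams plate_curves
#' @param effect effect level for the CI / isobologram (default 0.5).
#' @return list of class `plate_analysis`: `fit_4pl_a`, `fit_4pl_b`,
#'   `fit_me_a`, `fit_me_b`, `ci` ([combination_index()] result),
#'   `isobologram` (data.frame), `design`.
#' @export
analyze_plates <- function(plates, top_conc_a = NULL, top_conc_b = NULL,
                           unit_a = "kBq/mL", unit_b = "uM", effect = 0.5) {
  cs <- plate_curves(plates, top_conc_a, top_conc_b, unit_a, unit_b)
  fit_4pl_a <- fit_4pl(cs$curve_a)
  fit_4pl_b <- fit_4pl(cs$curve_b)
  fit_me_a <- fit_median_effect(cs$curve_a)
  fit_me_b <- fit_median_effect(cs$curve_b)
  ci <- combination_index(cs$design, fit_me_a, fit_me_b, cs$mixtures,
                          effect = effect)
  iso <- isobologram_points(fit_me_a, fit_me_b, ci)
  structure(list(fit_4pl_a = fit_4pl_a, fit_4pl_b = fit_4pl_b,
                 fit_me_a = fit_me_a, fit_me_b = fit_me_b, ci = ci,
                 isobologram = iso, design = cs$design),
            class = "plate_analysis")
}

#' @export
print.plate_analysis <- function(x, ...) {
  print(x$fit_4pl_a); print(x$fit_4pl_b); print(x$ci)
  invisible(x)
}

#' Full in vivo efficacy analysis of a tumor-volume table
#'
#' Builds an [efficacy_study()], computes per-arm doubling times and
#' treatment-over-control ratios with Tukey-adjusted significance at the
#' reference day, and -- when arm dose metadata is supplied -- the Bliss
#' synergy table for every combination arm.
#'
#' @param tumor_volumes data.frame in the `tumor_volumes.csv` schema.
#' @param arms optional data.frame with `group`, `ttc_kbq_kg`, `ola_mg_kg`
#'   mapping arm labels to component doses (the vehicle arm has both 0).
#' @param vehicle_group vehicle arm label.
#' @param reference_day day for T/C; default [default_reference_day()].
#' @param convention,margin Bliss settings (see [bliss_expected()],
#'   [bliss_call()]).
#' @param endpoint_mm3 humane-endpoint volume.
#' @return list of class `efficacy_analysis`: `study`, `reference_day`,
#'   `tc` (data.frame per arm), `doubling` (data.frame per arm), `bliss`
#'   (data.frame or NULL).
#' @export
analyze_efficacy <- function(tumor_volumes, arms = NULL,
                             vehicle_group = "vehicle", reference_day = NULL,
                             convention = "inhibition-scale", margin = 0.10,
                             endpoint_mm3 = 1500) {
  study <- efficacy_study(tumor_volumes, vehicle_group = vehicle_group,
                          endpoint_mm3 = endpoint_mm3)
  if (is.null(reference_day)) reference_day <- default_reference_day(study)
  treated <- setdiff(study$groups, vehicle_group)
  tc <- do.call(rbind, lapply(treated, function(g) {
    r <- tc_ratio(study, g, reference_day)
    data.frame(group = g, reference_day = reference_day,
               t_over_c = r$t_over_c, p_value = r$p_value,
               significant = r$significant)
  }))
  doubling <- do.call(rbind, lapply(study$groups, function(g) {
    dt <- doubling_time(study, g)
    data.frame(group = g, doubling_days = dt$days,
               n_no_growth = dt$n_no_growth)
  }))
  bliss <- NULL
  if (!is.null(arms)) {
    stopifnot(all(c("group", "ttc_kbq_kg", "ola_mg_kg") %in% names(arms)))
    tc_all <- rbind(tc[, c("group", "t_over_c")],
                    data.frame(group = vehicle_group, t_over_c = 1))
    tab <- merge(arms, tc_all, by = "group")
    tab$model <- "study"
    names(tab)[names(tab) == "ola_mg_kg"] <- "olaparib_mg_kg"
    if (any(tab$ttc_kbq_kg > 0 & tab$olaparib_mg_kg > 0)) {
      bliss <- bliss_from_tc_table(tab, convention = convention,
                                   margin = margin)
      combo <- tab$ttc_kbq_kg > 0 & tab$olaparib_mg_kg > 0
      bliss <- merge(tab[combo, c("group", "ttc_kbq_kg", "olaparib_mg_kg")],
                     bliss, by = c("ttc_kbq_kg", "olaparib_mg_kg"))
    }
  }
  structure(list(study = study, reference_day = reference_day, tc = tc,
                 doubling = doubling, bliss = bliss),
            class = "efficacy_analysis")
}

#' @export
print.efficacy_analysis <- function(x, ...) {
  cat(sprintf("<efficacy_analysis> reference day %g\n", x$reference_day))
  print(x$tc, row.names = FALSE)
  if (!is.null(x$bliss)) {
    cat("Bliss calls:\n")
    print(x$bliss[, c("group", "expected_tc", "observed_tc", "call")],
          row.names = FALSE)
  }
  invisible(x)
}
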