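#' Simulation spec: in vitro viability plates
#'
#' Describes a fixed-ratio combination plate experiment: two agents with
#' 4PL monotherapy dose-response, nine fixed-ratio mixtures, and a
#' one-parameter Bliss-interaction exponent `gamma` acting on the combination
#' survival surface,
#' \deqn{s(d_1, d_2) = (s_A(d_1)\, s_B(d_2))^{\gamma},}
#' so `gamma = 1` is exactly Bliss-independent, `gamma > 1` synergistic and
#' `gamma < 1` antagonistic. Measurement noise is additive Gaussian on the
#' viability fraction, then converted to raw signal.
#'
#' Default agent parameters emulate the radioconjugate / PARP-inhibitor pair
#' in the sensitive (BRCA2-deficient) line: IC50 3 kBq/mL for agent A
#' titrated 0.01-50 kBq/mL, IC50 0.03 uM for agent B titrated 0.01-25 uM,
#' unit Hill slopes. Mixture wells are titrated as fractions of the two top
#' concentrations, log-spaced around each ratio's analytic 50%-effect
#' fraction (as an experimenter would center a titration on the active
#' range).
#'
#' @param agent_a,agent_b lists with `top`, `bottom`, `hill`, `ec50`.
#' @param top_conc_a,top_conc_b top concentrations of the two titrations.
#' @param grid_a,grid_b single-agent concentration grids (default log-spaced
#'   from 0.01 to the top, `n_doses` points).
#' @param n_doses points per titration.
#' @param weights fixed-ratio weight pairs (default the nine standard pairs).
#' @param gamma interaction exponent, >= 0.
#' @param noise_sd additive Gaussian noise sd on the viability fraction.
#' @param replicates wells per concentration.
#' @param control_signal,blank_signal raw-signal anchors.
#' @param n_controls,n_blanks numbers of control and blank wells.
#' @param seed RNG seed used by [gen_viability_plates()].
#' @return Object of class `plate_sim_spec`.
#' @export
plate_sim_spec <- function(agent_a = list(top = 1, bottom = 0, hill = 1, ec50 = 3),
                           agent_b = list(top = 1, bottom = 0, hill = 1, ec50 = 0.03),
                           top_conc_a = 50, top_conc_b = 25,
                           grid_a = NULL, grid_b = NULL, n_doses = 9,
                           weights = default_ratio_weights(),
                           gamma = 1, noise_sd = 0, replicates = 3,
                           control_signal = 20000, blank_signal = 500,
                           n_controls = 16, n_blanks = 8, seed = 1) {
  for (p in list(agent_a, agent_b))
    stopifnot(all(c("top", "bottom", "hill", "ec50") %in% names(p)),
              p$ec50 > 0)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  stopifnot(top_conc_a > 0, top_conc_b > 0, replicates >= 1,
            control_signal > blank_signal)
  if (is.null(grid_a))
    grid_a <- 10^seq(log10(0.01), log10(top_conc_a), length.out = n_doses)
  if (is.null(grid_b))
    grid_b <- 10^seq(log10(0.01), log10(top_conc_b), length.out = n_doses)
  structure(list(agent_a = agent_a, agent_b = agent_b,
                 top_conc_a = top_conc_a, top_conc_b = top_conc_b,
                 grid_a = grid_a, grid_b = grid_b, n_doses = n_doses,
                 weights = as.matrix(weights), gamma = gamma,
                 noise_sd = noise_sd, replicates = replicates,
                 control_signal = control_signal, blank_signal = blank_signal,
                 n_controls = n_controls, n_blanks = n_blanks, seed = seed),
            class = "plate_sim_spec")
}

# 4PL survival for a parameter list
pl4 <- function(p, d) p$bottom + (p$top - p$bottom) / (1 + (d / p$ec50)^p$hill)

#' True combination survival surface of a plate simulation
#'
#' The noise-free surface `(sA(d1) * sB(d2))^gamma` the generator samples
#' from; useful as an independent oracle.
#'
#' @param spec a [plate_sim_spec()].
#' @param dose_a,dose_b native-unit doses (vectorized).
#' @return Survival fractions.
#' @export
plate_true_survival <- function(spec, dose_a, dose_b) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  (pl4(spec$agent_a, dose_a) * pl4(spec$agent_b, dose_b))^spec$gamma
}

# analytic fraction-of-top reaching `effect` for one weight pair (oracle
# used only to center the simulated titration on the active range)
plate_true_f50 <- function(spec, w_a, w_b, effect = 0.5) {
  g <- function(f) plate_true_survival(spec, f * w_a * spec$top_conc_a,
                                       f * w_b * spec$top_conc_b) -
    (1 - effect)
  stats::uniroot(g, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic fixed-ratio viability plate table
#'
#' Emits single-agent titrations, one mixture titration per weight pair,
#' untreated control wells and cell-free blank wells in the `plates.csv`
#' schema. Output is a pure function of `(spec, seed)`. Noisy viability is
#' clipped to `[0, 1.2]` before conversion to raw signal.
#'
#' @param spec a [plate_sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame with columns `well`, `agent_a_conc`, `agent_b_conc`,
#'   `mixture_weight_a`, `raw_signal`, `is_control`, `is_blank`; the
#'   simulation ground truth is attached as attribute `"truth"`.
#' @export
gen_viability_plates <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  withr_seed(seed)
  rows <- list()
  add <- function(da, db, wa, v) {
    rows[[length(rows) + 1L]] <<- data.frame(
      agent_a_conc = unname(da), agent_b_conc = unname(db),
      mixture_weight_a = unname(wa), viability = unname(v),
      is_control = FALSE, is_blank = FALSE)
  }
  rep_each <- function(x) rep(x, each = spec$replicates)

  # single agents
  da <- rep_each(spec$grid_a)
  add(da, 0, NA_real_, pl4(spec$agent_a, da))
  db <- rep_each(spec$grid_b)
  add(0, db, NA_real_, pl4(spec$agent_b, db))

  # fixed-ratio mixtures, titrated around each ratio's active range
  for (i in seq_len(nrow(spec$weights))) {
    w <- spec$weights[i, ]
    f50 <- plate_true_f50(spec, w[1], w[2])
    f <- rep_each(f50 * 10^seq(-1.2, 1.2, length.out = spec$n_doses))
    d1 <- f * w[1] * spec$top_conc_a
    d2 <- f * w[2] * spec$top_conc_b
    add(d1, d2, w[1], plate_true_survival(spec, d1, d2))
  }

  # controls and blanks
  rows[[length(rows) + 1L]] <- data.frame(
    agent_a_conc = 0, agent_b_conc = 0, mixture_weight_a = NA_real_,
    viability = rep(1, spec$n_controls), is_control = TRUE, is_blank = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    agent_a_conc = 0, agent_b_conc = 0, mixture_weight_a = NA_real_,
    viability = rep(0, spec$n_blanks), is_control = FALSE, is_blank = TRUE)

  tbl <- do.call(rbind, rows)
  v <- tbl$viability + stats::rnorm(nrow(tbl), 0, spec$noise_sd)
  v <- pmin(pmax(v, 0), 1.2)
  tbl$raw_signal <- spec$blank_signal +
    v * (spec$control_signal - spec$blank_signal)
  tbl$viability <- NULL
  tbl <- cbind(well = sprintf("W%04d", seq_len(nrow(tbl))), tbl)
  attr(tbl, "truth") <- list(
    agent_a = spec$agent_a, agent_b = spec$agent_b, gamma = spec$gamma,
    top_conc_a = spec$top_conc_a, top_conc_b = spec$top_conc_b,
    weights = spec$weights, noise_sd = spec$noise_sd, seed = seed)
  tbl
}

#' Simulation spec: xenograft efficacy study
#'
#' Tumor volumes follow exponential growth with dose-dependent kill terms,
#' \deqn{V(t) = V_0 \exp\!\big(g t - \psi_{arm} K(t)\big),}
#' where the kill integral `K(t)` combines a radioconjugate term that decays
#' with the Th-227 half-life,
#' `k_ttc * dose * (1 - exp(-lambda t)) / lambda`, and a PARP-inhibitor term
#' active during the dosing window, `k_ola * dose * min(t, window)`. The
#' interaction multiplier `psi` scales the total kill in arms receiving both
#' agents (`psi = 1`: Bliss-additive kill; `psi > 1`: synergistic).
#' Measurements carry multiplicative lognormal noise (mean-one) and animals
#' are censored at their first measurement at or above the humane-endpoint
#' volume.
#'
#' Defaults emulate the published study design: start volume 90 mm3, in vivo
#' doubling time 8.3 days, 10 animals per arm measured twice weekly for
#' 4 weeks, endpoint 1500 mm3, and kill rates placing the 600/300/125 kBq/kg
#' monotherapy T/C near 0.3/0.5/0.8 and olaparib 50 mg/kg near 0.5 at
#' day 21.
#'
#' @param v0 initial tumor volume, mm3.
#' @param growth exponential growth rate per day (default `ln 2 / 8.3`).
#' @param arms data.frame with `group`, `ttc_kbq_kg`, `ola_mg_kg`.
#' @param k_ttc kill rate per (kBq/kg) per day at injection time.
#' @param k_ola kill rate per (mg/kg) per day during the dosing window.
#' @param psi interaction multiplier on the combined kill (both agents).
#' @param noise_sd lognormal sdlog of measurement noise.
#' @param n_per_arm animals per arm.
#' @param days measurement days (twice weekly by default).
#' @param dosing_window PARP-inhibitor dosing window, days.
#' @param endpoint humane-endpoint volume, mm3.
#' @param th_half_life_d Th-227 half-life in days.
#' @param seed RNG seed used by [gen_xenograft_study()].
#' @return Object of class `xeno_sim_spec`.
#' @export
xeno_sim_spec <- function(v0 = 90, growth = log(2) / 8.3,
                          arms = default_xeno_arms(),
                          k_ttc = 1.376e-4, k_ola = 6.6e-4, psi = 1,
                          noise_sd = 0.1, n_per_arm = 10,
                          days = c(0, 3, 7, 10, 14, 17, 21, 24, 28),
                          dosing_window = 28, endpoint = 1500,
                          th_half_life_d = 18.7, seed = 1) {
  stopifnot(v0 > 0, growth > 0, k_ttc >= 0, k_ola >= 0, psi >= 0,
            noise_sd >= 0, n_per_arm >= 1, endpoint > 0, th_half_life_d > 0)
  if (!length(days)) stop("`days` must not be empty", call. = FALSE)
  stopifnot(all(c("group", "ttc_kbq_kg", "ola_mg_kg") %in% names(arms)))
  structure(list(v0 = v0, growth = growth, arms = arms, k_ttc = k_ttc,
                 k_ola = k_ola, psi = psi, noise_sd = noise_sd,
                 n_per_arm = n_per_arm, days = sort(unique(days)),
                 dosing_window = dosing_window, endpoint = endpoint,
                 th_half_life_d = th_half_life_d, seed = seed),
            class = "xeno_sim_spec")
}

#' Default xenograft arms (vehicle, monotherapies, combinations)
#' @return data.frame with `group`, `ttc_kbq_kg`, `ola_mg_kg`.
#' @export
default_xeno_arms <- function() {
  data.frame(
    group = c("vehicle", "ttc125", "ttc300", "ttc600", "ola25", "ola50",
              "ttc125+ola25", "ttc125+ola50", "ttc300+ola25", "ttc300+ola50"),
    ttc_kbq_kg = c(0, 125, 300, 600, 0, 0, 125, 125, 300, 300),
    ola_mg_kg = c(0, 0, 0, 0, 25, 50, 25, 50, 25, 50))
}

# integrated kill K(t) for one arm (without psi)
xeno_kill_integral <- function(spec, ttc, ola, day) {
  lam <- log(2) / spec$th_half_life_d
  spec$k_ttc * ttc * (1 - exp(-lam * day)) / lam +
    spec$k_ola * ola * pmin(day, spec$dosing_window)
}

#' Model-true treatment-over-control ratio of a simulated arm
#'
#' The noise-free vehicle-normalized volume ratio
#' `exp(-psi_arm * K(day))`; the quantity the analysis pipeline estimates.
#'
#' @param spec a [xeno_sim_spec()].
#' @param group arm label present in `spec$arms`.
#' @param day study day.
#' @return True T/C ratio.
#' @export
xeno_true_tc <- function(spec, group, day) {
  stopifnot(inherits(spec, "xeno_sim_spec"))
  a <- spec$arms[spec$arms$group == group, , drop = FALSE]
  if (nrow(a) != 1L) stop("unknown arm '", group, "'", call. = FALSE)
  psi_arm <- if (a$ttc_kbq_kg > 0 && a$ola_mg_kg > 0) spec$psi else 1
  exp(-psi_arm * xeno_kill_integral(spec, a$ttc_kbq_kg, a$ola_mg_kg, day))
}

#' Generate a synthetic xenograft tumor-volume table
#'
#' @param spec a [xeno_sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame in the `tumor_volumes.csv` schema (`animal_id`,
#'   `group`, `day`, `volume_mm3`, `body_weight_g`), rows after an animal's
#'   humane-endpoint censoring removed. Attributes: `"censoring"`
#'   (data.frame `animal_id`, `day`, `reason`) and `"truth"` (arm-level true
#'   T/C at the last study day plus the generating parameters).
#' @export
gen_xenograft_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "xeno_sim_spec"))
  withr_seed(seed)
  sd <- spec$noise_sd
  rows <- list(); cens <- list()
  for (i in seq_len(nrow(spec$arms))) {
    a <- spec$arms[i, ]
    psi_arm <- if (a$ttc_kbq_kg > 0 && a$ola_mg_kg > 0) spec$psi else 1
    vtrue <- spec$v0 * exp(spec$growth * spec$days -
                             psi_arm * xeno_kill_integral(spec, a$ttc_kbq_kg,
                                                          a$ola_mg_kg,
                                                          spec$days))
    for (j in seq_len(spec$n_per_arm)) {
      id <- sprintf("%s-%02d", a$group, j)
      noise <- exp(stats::rnorm(length(spec$days), -sd^2 / 2, sd))
      vol <- vtrue * noise
      bw <- 25 * exp(stats::rnorm(length(spec$days), 0, 0.02))
      hit <- which(vol >= spec$endpoint)
      keep <- seq_along(spec$days)
      if (length(hit)) {
        keep <- seq_len(hit[1L])
        cens[[length(cens) + 1L]] <- data.frame(
          animal_id = id, day = spec$days[hit[1L]],
          reason = sprintf("tumor volume >= %g mm3", spec$endpoint))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, group = a$group, day = spec$days[keep],
        volume_mm3 = vol[keep], body_weight_g = bw[keep])
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  last <- max(spec$days)
  attr(tbl, "censoring") <- if (length(cens)) do.call(rbind, cens) else
    data.frame(animal_id = character(), day = numeric(), reason = character())
  attr(tbl, "truth") <- list(
    true_tc = stats::setNames(
      vapply(spec$arms$group, function(g) xeno_true_tc(spec, g, last),
             numeric(1)),
      spec$arms$group),
    day = last, psi = spec$psi, growth = spec$growth, v0 = spec$v0,
    seed = seed)
  tbl
}

#' Simulation spec: biodistribution time course
#'
#' Decay-corrected activity concentration curves (in %IA/g): blood follows a
#' bi-exponential washout
#' `a1 * 2^(-t/t1) + a2 * 2^(-t/t2)`, tumor a saturating uptake
#' `plateau * (1 - exp(-k_up * t))`. In `"targeted"` mode the tumor plateau
#' emulates specific antibody-mediated uptake (default 50 %IA/g); in
#' `"isotype"` mode only passive uptake remains (default 5 %IA/g). Measured
#' activities are forward-decayed with the Th-227 half-life and carry
#' lognormal per-sample noise.
#'
#' @param mode `"targeted"` or `"isotype"`.
#' @param blood list `a1`, `t1`, `a2`, `t2` (%IA/g amplitudes, half-times h).
#' @param tumor_plateau tumor plateau %IA/g (defaults by mode).
#' @param k_up tumor uptake rate per hour.
#' @param times harvest times, hours post-injection.
#' @param n_per_time animals per harvest time.
#' @param cv lognormal coefficient of variation of a measurement.
#' @param injected_bq injected activity per animal (Bq).
#' @param tumor_mass_g,blood_mass_g nominal sample masses.
#' @param th_half_life_d Th-227 half-life, days.
#' @param seed RNG seed used by [gen_biodistribution()].
#' @return Object of class `biodist_sim_spec`.
#' @export
biodist_sim_spec <- function(mode = c("targeted", "isotype"),
                             blood = list(a1 = 30, t1 = 12, a2 = 12, t2 = 200),
                             tumor_plateau = NULL, k_up = 0.0089,
                             times = c(24, 72, 168, 336), n_per_time = 3,
                             cv = 0.1, injected_bq = 18000,
                             tumor_mass_g = 0.25, blood_mass_g = 0.2,
                             th_half_life_d = 18.7, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(tumor_plateau))
    tumor_plateau <- if (mode == "targeted") 50 else 5
  stopifnot(tumor_plateau > 0, k_up > 0, all(times >= 0), n_per_time >= 1,
            cv >= 0, injected_bq > 0, tumor_mass_g > 0, blood_mass_g > 0)
  if (mode == "isotype" && tumor_plateau > 10)
    stop("isotype-mode tumor plateau must stay at passive-uptake levels",
         call. = FALSE)
  structure(list(mode = mode, blood = blood, tumor_plateau = tumor_plateau,
                 k_up = k_up, times = sort(times), n_per_time = n_per_time,
                 cv = cv, injected_bq = injected_bq,
                 tumor_mass_g = tumor_mass_g, blood_mass_g = blood_mass_g,
                 th_half_life_d = th_half_life_d, seed = seed),
            class = "biodist_sim_spec")
}

#' Analytic %IA/g curve of a biodistribution simulation
#'
#' @param spec a [biodist_sim_spec()].
#' @param organ `"tumor"` or `"blood"`.
#' @param time_h hours post-injection (vectorized).
#' @return Decay-corrected %IA/g.
#' @export
biodist_true_curve <- function(spec, organ = c("tumor", "blood"), time_h) {
  stopifnot(inherits(spec, "biodist_sim_spec"))
  organ <- match.arg(organ)
  if (organ == "tumor")
    spec$tumor_plateau * (1 - exp(-spec$k_up * time_h))
  else
    spec$blood$a1 * 2^(-time_h / spec$blood$t1) +
      spec$blood$a2 * 2^(-time_h / spec$blood$t2)
}

#' Generate a synthetic biodistribution table
#'
#' @param spec a [biodist_sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame in the `biodistribution.csv` schema (`animal_id`,
#'   `group`, `organ`, `time_h`, `activity_bq`, `mass_g`, `injected_bq`).
#'   Attribute `"truth"` carries the analytic curves' tumor/blood ratio at
#'   the last harvest time and the generating parameters.
#' @export
gen_biodistribution <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "biodist_sim_spec"))
  withr_seed(seed)
  th <- nuclide("Th-227", spec$th_half_life_d, "days")
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- list()
  for (t in spec$times) {
    for (j in seq_len(spec$n_per_time)) {
      id <- sprintf("%s-%03dh-%02d", spec$mode, t, j)
      for (organ in c("tumor", "blood")) {
        mass0 <- if (organ == "tumor") spec$tumor_mass_g else spec$blood_mass_g
        mass <- mass0 * exp(stats::rnorm(1, 0, 0.1))
        pct <- biodist_true_curve(spec, organ, t)
        act <- pct / 100 * spec$injected_bq * mass
        act <- forward_decay(act, t, th) *
          exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = spec$mode, organ = organ, time_h = t,
          activity_bq = act, mass_g = mass, injected_bq = spec$injected_bq)
      }
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  tmax <- max(spec$times)
  attr(tbl, "truth") <- list(
    tumor_blood_ratio = biodist_true_curve(spec, "tumor", tmax) /
      biodist_true_curve(spec, "blood", tmax),
    time_h = tmax, mode = spec$mode, tumor_plateau = spec$tumor_plateau,
    seed = seed)
  tbl
}

#' Simulation spec: hematology time course
#'
#' Cell counts per lineage follow a smooth suppression-recovery excursion,
#' \deqn{c(t) = baseline \cdot (1 - depth \cdot g(t)),\quad
#'       g(t) = \exp\!\left(-\frac{\ln^2(t/t_{nadir})}{2\sigma^2}\right),}
#' a lognormal-shaped dip equal to `depth` at the programmed nadir day and
#' back within 10% of baseline at the programmed recovery day (`sigma` is
#' derived from the nadir/recovery days at the reference depth). Depth
#' scales linearly with the arm's radioconjugate activity dose; the
#' PARP-inhibitor dose does not suppress counts, and red blood cells are
#' unaffected by default. Noise is lognormal per sample.
#'
#' @param arms data.frame with `group`, `ttc_kbq_kg`.
#' @param baselines named list of baseline counts: `platelets_1e9_per_l`,
#'   `wbc_1e9_per_l`, `rbc_1e12_per_l`.
#' @param nadir named list per lineage: `day`, `recovery`, `depth_at_ref`
#'   (fraction of baseline lost at the reference dose; 0 = unaffected).
#' @param ref_dose radioconjugate dose (kBq/kg) producing `depth_at_ref`.
#' @param days sampling days (every other week by default).
#' @param n_per_arm animals per arm.
#' @param cv lognormal coefficient of variation per sample.
#' @param seed RNG seed used by [gen_hematology()].
#' @return Object of class `heme_sim_spec`.
#' @export
heme_sim_spec <- function(arms = data.frame(group = c("vehicle", "ttc600"),
                                            ttc_kbq_kg = c(0, 600)),
                          baselines = list(platelets_1e9_per_l = 1000,
                                           wbc_1e9_per_l = 8,
                                           rbc_1e12_per_l = 9),
                          nadir = list(
                            platelets_1e9_per_l = list(day = 12, recovery = 26,
                                                       depth_at_ref = 0.5),
                            wbc_1e9_per_l = list(day = 11, recovery = 39,
                                                 depth_at_ref = 0.6),
                            rbc_1e12_per_l = list(day = 12, recovery = 26,
                                                  depth_at_ref = 0)),
                          ref_dose = 600, days = seq(0, 42, by = 14),
                          n_per_arm = 5, cv = 0.05, seed = 1) {
  stopifnot(all(c("group", "ttc_kbq_kg") %in% names(arms)),
            all(names(baselines) %in% names(nadir)),
            ref_dose > 0, n_per_arm >= 1, cv >= 0, all(days >= 0))
  for (lin in names(nadir)) {
    nd <- nadir[[lin]]
    stopifnot(all(c("day", "recovery", "depth_at_ref") %in% names(nd)))
    if (nd$depth_at_ref > 0)
      stopifnot(nd$day > 0, nd$recovery > nd$day, nd$depth_at_ref <= 1)
  }
  structure(list(arms = arms, baselines = baselines, nadir = nadir,
                 ref_dose = ref_dose, days = sort(unique(days)),
                 n_per_arm = n_per_arm, cv = cv, seed = seed),
            class = "heme_sim_spec")
}

# suppression bump g(t) in [0, 1], 1 at the nadir day; width set so the
# excursion is back to 0.1/depth_at_ref of baseline loss at the recovery day
heme_bump <- function(t, nd) {
  if (nd$depth_at_ref <= 0.1) return(rep(0, length(t)))
  sigma <- log(nd$recovery / nd$day) / sqrt(2 * log(nd$depth_at_ref / 0.1))
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-log(t[pos] / nd$day)^2 / (2 * sigma^2))
  out
}

#' True (noise-free) hematology count of a simulated arm
#'
#' @param spec a [heme_sim_spec()].
#' @param group arm label.
#' @param lineage lineage column name.
#' @param day sampling day (vectorized).
#' @return Expected count.
#' @export
heme_true_count <- function(spec, group, lineage, day) {
  stopifnot(inherits(spec, "heme_sim_spec"))
  a <- spec$arms[spec$arms$group == group, , drop = FALSE]
  if (nrow(a) != 1L) stop("unknown arm '", group, "'", call. = FALSE)
  nd <- spec$nadir[[lineage]]
  depth <- nd$depth_at_ref * a$ttc_kbq_kg / spec$ref_dose
  spec$baselines[[lineage]] * (1 - depth * heme_bump(day, nd))
}

#' Generate a synthetic hematology table
#'
#' @param spec a [heme_sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame in the `hematology.csv` schema (`animal_id`, `group`,
#'   `day`, plus one column per lineage). Attribute `"truth"` carries the
#'   programmed nadir parameters.
#' @export
gen_hematology <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "heme_sim_spec"))
  withr_seed(seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- list()
  for (i in seq_len(nrow(spec$arms))) {
    g <- spec$arms$group[i]
    for (j in seq_len(spec$n_per_arm)) {
      row <- data.frame(animal_id = sprintf("%s-%02d", g, j), group = g,
                        day = spec$days)
      for (lin in names(spec$baselines)) {
        mu <- heme_true_count(spec, g, lin, spec$days)
        row[[lin]] <- mu * exp(stats::rnorm(length(spec$days),
                                            -sdlog^2 / 2, sdlog))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  attr(tbl, "truth") <- list(nadir = spec$nadir, ref_dose = spec$ref_dose,
                             seed = seed)
  tbl
}

withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
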