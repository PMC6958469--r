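make_study <- function(groups, n = 4, days = c(0, 7, 14, 21), f = NULL,
                       sd = 0, seed = 1) {
  set.seed(seed)
  if (is.null(f)) f <- function(g, t) 90 * 2^(t / 7)
  rows <- list()
  for (g in names(groups)) for (j in seq_len(n)) {
    v <- groups[[g]](days) * exp(rnorm(length(days), 0, sd))
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = sprintf("%s-%d", g, j), group = g, day = days,
      volume_mm3 = v)
  }
  do.call(rbind, rows)
}

test_that("doubling time inverts exact exponential growth", {
  t <- seq(0, 28, by = 3.5)
  expect_equal(doubling_time(90 * 2^(t / 7.3), day = t)$days, 7.3,
               tolerance = 1e-10)
  flat <- doubling_time(rep(100, 5), day = seq(0, 28, by = 7))
  expect_true(is.na(flat$days))
  expect_identical(flat$status, "no growth")
  expect_error(doubling_time(c(100, 120), day = c(0, 7)), "3 time points")
})

test_that("group doubling time recovers the programmed rate from noisy data", {
  spec <- xeno_sim_spec(growth = log(2) / 8.3, noise_sd = 0.1,
                        n_per_arm = 10,
                        arms = data.frame(group = "vehicle", ttc_kbq_kg = 0,
                                          ola_mg_kg = 0),
                        seed = 11)
  tv <- gen_xenograft_study(spec)
  st <- efficacy_study(tv)
  dt <- doubling_time(st, "vehicle")
  expect_equal(dt$days, 8.3, tolerance = 0.15 * 8.3)
  # noiseless arm is exact
  tv0 <- gen_xenograft_study(xeno_sim_spec(growth = log(2) / 8.3,
                                           noise_sd = 0, n_per_arm = 2,
                                           arms = spec$arms))
  expect_equal(doubling_time(efficacy_study(tv0), "vehicle")$days, 8.3,
               tolerance = 1e-8)
})

test_that("humane-endpoint censoring removes animals from later group means", {
  d <- data.frame(
    animal_id = rep(c("v-1", "v-2", "t-1"), each = 3),
    group = rep(c("vehicle", "vehicle", "ttc"), each = 3),
    day = rep(c(0, 7, 14), 3),
    volume_mm3 = c(100, 800, 1200, 100, 1600, 2400, 100, 90, 80))
  st <- efficacy_study(d)
  expect_identical(st$censoring$animal_id, "v-2")
  expect_identical(st$censoring$day, 7)
  # day 14 vehicle mean excludes the censored animal (its 1600 row kept)
  expect_equal(default_reference_day(st), 7)
  tc <- tc_ratio(st, "ttc", reference_day = 14)
  expect_equal(tc$t_over_c, 80 / 1200)
  expect_identical(tc$n_vehicle, 1L)
})

test_that("treatment-over-control ratio is exact on constructed means", {
  g <- list(vehicle = function(t) rep(1400, length(t)),
            ttc = function(t) rep(140, length(t)))
  st <- efficacy_study(make_study(g, sd = 0))
  expect_error(tc_ratio(st, "ttc"), NA)
  expect_equal(tc_ratio(st, "ttc", reference_day = 21)$t_over_c, 0.1)
  g2 <- list(vehicle = function(t) 90 * 2^(t / 7),
             same = function(t) 90 * 2^(t / 7))
  expect_equal(tc_ratio(efficacy_study(make_study(g2)), "same",
                        reference_day = 21)$t_over_c, 1)
})

test_that("ANOVA/Tukey separates groups as expected in null and strong cases", {
  set.seed(42)
  null_df <- data.frame(
    animal_id = sprintf("a%d", 1:20),
    group = rep(c("vehicle", "ttc"), each = 10),
    day = 21, volume_mm3 = rnorm(20, 500, 80))
  at <- anova_tukey(efficacy_study(null_df), 21)
  expect_gt(at$p_adj[at$group == "ttc"], 0.05)

  sep_df <- data.frame(
    animal_id = sprintf("a%d", 1:20),
    group = rep(c("vehicle", "ttc"), each = 10),
    day = 21, volume_mm3 = c(rnorm(10, 1000, 1), rnorm(10, 100, 1)))
  at2 <- anova_tukey(efficacy_study(sep_df), 21)
  expect_lt(at2$p_adj[at2$group == "ttc"], 1e-6)

  const <- data.frame(animal_id = sprintf("a%d", 1:8),
                      group = rep(c("vehicle", "ttc"), each = 4),
                      day = 0, volume_mm3 = rep(c(500, 100), each = 4))
  expect_error(anova_tukey(efficacy_study(const), 0), "degenerate")
})

test_that("Tukey p-values rank pairs like an exhaustive permutation oracle", {
  set.seed(7)
  df <- data.frame(
    animal_id = sprintf("a%d", 1:12),
    group = rep(c("vehicle", "low", "high"), each = 4),
    day = 21,
    volume_mm3 = c(rnorm(4, 800, 120), rnorm(4, 600, 120), rnorm(4, 250, 120)))
  at <- anova_tukey(efficacy_study(df), 21)
  p_low <- perm_p(df$volume_mm3[df$group == "low"],
                  df$volume_mm3[df$group == "vehicle"])
  p_high <- perm_p(df$volume_mm3[df$group == "high"],
                   df$volume_mm3[df$group == "vehicle"])
  # same ordering of the two contrasts under both procedures
  expect_identical(order(c(p_low, p_high)),
                   order(c(at$p_adj[at$group == "low"],
                           at$p_adj[at$group == "high"])))
})

test_that("Bliss expectation follows both conventions and validates input", {
  expect_equal(bliss_expected(0.5, 0.5, "paper-literal"), 0.75)
  expect_equal(bliss_expected(0.8, 0.5), 0.40)
  expect_equal(bliss_expected(0, 0.7), 0)
  expect_equal(bliss_expected(0, 0.7, "paper-literal"), 0.7)
  expect_warning(out <- bliss_expected(1.2, 0.5), "clamped")
  expect_equal(out, 0.5)
  expect_error(bliss_expected(1.6, 0.5), "\\[0, 1.5\\]")
  expect_error(bliss_expected(-0.1, 0.5), "\\[0, 1.5\\]")
})

test_that("Bliss expectation bounds hold across the unit square", {
  a <- runif(200); b <- runif(200)
  expect_true(all(bliss_expected(a, b) <= pmin(a, b) + 1e-12))
  expect_true(all(bliss_expected(a, b, "paper-literal") >=
                    pmax(a, b) - 1e-12))
})

test_that("Bliss calls respect the margin and are monotone in observed T/C", {
  expect_identical(bliss_call(0.40, 0.10), "synergistic")
  expect_identical(bliss_call(0.50, 0.45), "additive")
  expect_identical(bliss_call(0.30, 0.45), "antagonistic")
  # boundary values are additive
  expect_identical(bliss_call(0.40, 0.30), "additive")
  expect_identical(bliss_call(0.40, 0.50), "additive")
  rank <- c(synergistic = 1, additive = 2, antagonistic = 3)
  for (e in seq(0.05, 0.95, by = 0.1)) {
    calls <- rank[bliss_call(e, seq(0, 1.2, by = 0.01))]
    expect_true(all(diff(calls) >= 0))
  }
  expect_error(bliss_call(0.4, 0.1, margin = 0.6), "margin")
})

test_that("analyze_efficacy assembles T/C, significance, and Bliss calls", {
  spec <- xeno_sim_spec(
    arms = data.frame(group = c("vehicle", "a", "b", "ab"),
                      ttc_kbq_kg = c(0, 300, 0, 300),
                      ola_mg_kg = c(0, 0, 50, 50)),
    n_per_arm = 8, noise_sd = 0.08, psi = 1, seed = 5)
  tv <- gen_xenograft_study(spec)
  ea <- analyze_efficacy(tv, arms = spec$arms)
  expect_setequal(ea$tc$group, c("a", "b", "ab"))
  expect_identical(nrow(ea$bliss), 1L)
  truth <- attr(tv, "truth")$true_tc
  expect_equal(ea$tc$t_over_c[ea$tc$group == "ab"], unname(truth["ab"]),
               tolerance = 0.25)
  expect_identical(ea$bliss$call, "additive")
})

test_that("hematology nadir and recovery find programmed features", {
  expect_equal(hematology_nadir(c(0, 12, 26), c(100, 50, 80)),
               list(day = 12, fraction = 0.5, baseline = 100, status = "ok"))
  flat <- hematology_nadir(c(0, 14, 28), c(100, 102, 101))
  expect_identical(flat$status, "no suppression")
  expect_equal(flat$fraction, 1.0)
  expect_equal(hematology_recovery(c(0, 12, 26), c(100, 50, 95))$day, 26)
  nr <- hematology_recovery(c(0, 12, 26), c(100, 50, 70))
  expect_true(is.na(nr$day))
  expect_identical(nr$status, "no recovery")
})
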