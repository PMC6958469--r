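test_that("a drug combined with itself gives CI = 1 at every ratio", {
  for (h in c(0.5, 1, 2, 4)) {
    sham <- sham_combination(hill = h, ec50 = 5)
    fit <- fit_median_effect(sham$single)
    ci <- combination_index(sham$design, fit, fit, sham$mixtures)
    expect_true(all(abs(ci$per_ratio$ci - 1) <= 0.02))
    expect_equal(ci$average_ci, 1, tolerance = 0.02)
    expect_identical(ci$classification, "additive")
  }
})

test_that("CI is invariant under rescaling either agent's concentration unit", {
  sp <- plate_sim_spec(agent_a = list(top = 1, bottom = 0, hill = 1.4, ec50 = 3),
                       agent_b = list(top = 1, bottom = 0, hill = 0.8, ec50 = 0.4),
                       top_conc_a = 50, top_conc_b = 8, gamma = 1.2,
                       noise_sd = 0)
  pl <- gen_viability_plates(sp)
  base <- analyze_plates(pl)$ci
  for (k in c(1e3, 0.037)) {
    pl2 <- pl
    pl2$agent_a_conc <- pl2$agent_a_conc * k
    scaled <- analyze_plates(pl2)$ci
    expect_equal(scaled$per_ratio$ci, base$per_ratio$ci, tolerance = 1e-8)
    expect_equal(scaled$average_ci, base$average_ci, tolerance = 1e-8)
  }
})

test_that("pipeline CI matches a brute-force oracle on a Bliss surface", {
  # two hill-1 agents with median-effect doses 10 and 1, 50:50 weights
  sp <- plate_sim_spec(agent_a = list(top = 1, bottom = 0, hill = 1, ec50 = 10),
                       agent_b = list(top = 1, bottom = 0, hill = 1, ec50 = 1),
                       top_conc_a = 200, top_conc_b = 20,
                       weights = matrix(c(0.5, 0.5), nrow = 1),
                       gamma = 1, noise_sd = 0)
  an <- analyze_plates(gen_viability_plates(sp))
  expect_equal(an$ci$average_ci, oracle_ci(sp, 0.5, 0.5), tolerance = 0.02)
})

test_that("CI classification partitions the CI line without gaps", {
  ci <- c(0, 0.6, 0.8 - 1e-9, 0.8, 1, 1.2, 1.2 + 1e-9, 5)
  expect_identical(
    classify_ci(ci),
    c("synergistic", "synergistic", "synergistic", "additive", "additive",
      "additive", "antagonistic", "antagonistic"))
})

test_that("mixtures that never reach 50% effect are flagged and excluded", {
  sham <- sham_combination(hill = 1, ec50 = 5)
  fit <- fit_median_effect(sham$single)
  # replace one mixture by a weak titration topping out at 30% effect
  weak_f <- 10^seq(-4, -2, length.out = 9)
  sham$mixtures[[4]] <- dose_response_curve(
    weak_f, 1 / (1 + weak_f * 100 / 5), agent = "weak", unit = "fraction")
  expect_warning(
    ci <- combination_index(sham$design, fit, fit, sham$mixtures),
    "excluded")
  expect_identical(ci$n_excluded, 1L)
  expect_false(ci$per_ratio$evaluable[4])
  expect_equal(ci$average_ci, 1, tolerance = 0.02)
})

test_that("isobologram geometry reflects the combination index", {
  sham <- sham_combination(hill = 2, ec50 = 5)
  fit <- fit_median_effect(sham$single)
  ci <- combination_index(sham$design, fit, fit, sham$mixtures)
  iso <- isobologram_points(fit, fit, ci)
  ia <- iso$dose_a[iso$point == "intercept_a"]
  ib <- iso$dose_b[iso$point == "intercept_b"]
  expect_equal(ia, fit$dm, tolerance = 1e-8)
  mx <- iso[iso$point == "mixture", ]
  # sham points lie on the additivity line joining the intercepts
  expect_equal(mx$dose_a / ia + mx$dose_b / ib, rep(1, nrow(mx)),
               tolerance = 0.02)

  # synergistic interaction pushes every interior point below the line
  sp <- plate_sim_spec(agent_a = list(top = 1, bottom = 0, hill = 1, ec50 = 3),
                       agent_b = list(top = 1, bottom = 0, hill = 1, ec50 = 0.5),
                       top_conc_a = 60, top_conc_b = 10,
                       gamma = 1.5, noise_sd = 0)
  an <- analyze_plates(gen_viability_plates(sp))
  iso2 <- an$isobologram
  ia2 <- iso2$dose_a[iso2$point == "intercept_a"]
  ib2 <- iso2$dose_b[iso2$point == "intercept_b"]
  mx2 <- iso2[iso2$point == "mixture", ]
  expect_true(all(mx2$dose_a / ia2 + mx2$dose_b / ib2 < 1))
  # a point's normalized coordinate sum is its CI by construction
  expect_equal(mx2$dose_a / an$ci$d50_a + mx2$dose_b / an$ci$d50_b,
               an$ci$per_ratio$ci, tolerance = 1e-10)
})

test_that("the fixed-ratio design rejects malformed weights", {
  expect_error(fixed_ratio_design(1, 1, weights = cbind(c(0.5, 1), c(0.5, 0))),
               "weight pair")
  expect_error(fixed_ratio_design(1, 1, weights = cbind(0.6, 0.6)),
               "sum to 1")
  expect_equal(nrow(fixed_ratio_design(1, 1)$weights), 9L)
})
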