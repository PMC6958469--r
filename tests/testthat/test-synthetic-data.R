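test_that("all generators are pure functions of spec and seed", {
  expect_identical(gen_viability_plates(plate_sim_spec(noise_sd = 0.05, seed = 9)),
                   gen_viability_plates(plate_sim_spec(noise_sd = 0.05, seed = 9)))
  expect_identical(gen_xenograft_study(xeno_sim_spec(n_per_arm = 3, seed = 9)),
                   gen_xenograft_study(xeno_sim_spec(n_per_arm = 3, seed = 9)))
  expect_identical(gen_biodistribution(biodist_sim_spec(seed = 9)),
                   gen_biodistribution(biodist_sim_spec(seed = 9)))
  expect_identical(gen_hematology(heme_sim_spec(seed = 9)),
                   gen_hematology(heme_sim_spec(seed = 9)))
  # a different seed changes the noisy outputs
  a <- gen_xenograft_study(xeno_sim_spec(n_per_arm = 3, seed = 9))
  b <- gen_xenograft_study(xeno_sim_spec(n_per_arm = 3, seed = 10))
  expect_false(identical(a$volume_mm3, b$volume_mm3))
})

test_that("generator outputs validate against the consuming CSV schemas", {
  expect_true(validate_table(gen_viability_plates(plate_sim_spec(seed = 2)),
                             "plates")$ok)
  expect_true(validate_table(gen_xenograft_study(xeno_sim_spec(n_per_arm = 2,
                                                               seed = 2)),
                             "tumor_volumes")$ok)
  expect_true(validate_table(gen_biodistribution(biodist_sim_spec(seed = 2)),
                             "biodistribution")$ok)
  expect_true(validate_table(gen_hematology(heme_sim_spec(seed = 2)),
                             "hematology")$ok)
})

test_that("a Bliss-independent plate round-trips to the oracle CI", {
  # hill = 1 for both agents; gamma = 1 is the Bliss-null surface
  sp <- plate_sim_spec(gamma = 1, noise_sd = 0)
  an <- analyze_plates(gen_viability_plates(sp))
  oracle <- vapply(seq_len(nrow(sp$weights)), function(i)
    oracle_ci(sp, sp$weights[i, 1], sp$weights[i, 2]), numeric(1))
  expect_equal(an$ci$per_ratio$ci, oracle, tolerance = 0.03)
  # Bliss independence is mildly Loewe-synergistic, but classifies additive
  expect_identical(an$ci$classification, "additive")
  expect_true(all(an$ci$per_ratio$ci < 1))
})

test_that("a strong interaction exponent drives the CI into synergy", {
  sp <- plate_sim_spec(gamma = 1.6, noise_sd = 0)
  an <- analyze_plates(gen_viability_plates(sp))
  expect_lt(an$ci$average_ci, 0.8)
  expect_identical(an$ci$classification, "synergistic")
  oracle <- mean(vapply(seq_len(nrow(sp$weights)), function(i)
    oracle_ci(sp, sp$weights[i, 1], sp$weights[i, 2]), numeric(1)))
  expect_equal(an$ci$average_ci, oracle, tolerance = 0.03)
})

test_that("noise-free xenograft arms follow the programmed kinetics exactly", {
  spec <- xeno_sim_spec(noise_sd = 0, n_per_arm = 2, seed = 1)
  tv <- gen_xenograft_study(spec)
  st <- efficacy_study(tv)
  expect_equal(doubling_time(st, "vehicle")$days,
               log(2) / spec$growth, tolerance = 1e-8)
  day <- max(spec$days)
  for (g in c("ttc300", "ola50", "ttc300+ola50")) {
    tc <- tc_ratio(st, g, reference_day = day)
    expect_equal(tc$t_over_c, xeno_true_tc(spec, g, day), tolerance = 1e-10)
  }
  # an interaction multiplier deepens the combination kill only
  spec2 <- xeno_sim_spec(noise_sd = 0, n_per_arm = 2, psi = 2)
  expect_equal(xeno_true_tc(spec2, "ttc300+ola50", 21),
               xeno_true_tc(spec2, "ttc300", 21)^2 *
                 xeno_true_tc(spec2, "ola50", 21)^2, tolerance = 1e-12)
  expect_equal(xeno_true_tc(spec2, "ttc300", 21),
               xeno_true_tc(spec, "ttc300", 21))
})

test_that("xenograft censoring triggers at the humane-endpoint volume", {
  spec <- xeno_sim_spec(noise_sd = 0, n_per_arm = 2,
                        days = seq(0, 42, by = 3.5),
                        arms = data.frame(group = "vehicle", ttc_kbq_kg = 0,
                                          ola_mg_kg = 0))
  tv <- gen_xenograft_study(spec)
  cens <- attr(tv, "censoring")
  expect_identical(nrow(cens), 2L)
  # exponential growth from 90 mm3 at doubling 8.3 d crosses 1500 at ~33.7 d
  expect_true(all(cens$day == 35))
  expect_true(all(tapply(tv$day, tv$animal_id, max) == 35))
})

test_that("biodistribution pipeline recovers the analytic curves", {
  sp <- biodist_sim_spec(cv = 0, seed = 3)
  bd <- gen_biodistribution(sp)
  s <- biodist_summary(bd, th227)
  tumor336 <- s$mean_pct_ia_g[s$organ == "tumor" & s$time_h == 336]
  expect_equal(tumor336, biodist_true_curve(sp, "tumor", 336),
               tolerance = 0.02)
  expect_equal(tumor_to_blood(s, 336)$ratio,
               attr(bd, "truth")$tumor_blood_ratio, tolerance = 1e-8)
})

test_that("isotype-control uptake stays below targeted uptake in every run", {
  ratios <- vapply(1:50, function(s) {
    tg <- biodist_summary(gen_biodistribution(
      biodist_sim_spec("targeted", seed = s)), th227)
    iso <- biodist_summary(gen_biodistribution(
      biodist_sim_spec("isotype", seed = s + 1000)), th227)
    tumor_to_blood(iso, 336)$ratio < tumor_to_blood(tg, 336)$ratio
  }, logical(1))
  expect_true(all(ratios))
  expect_error(biodist_sim_spec("isotype", tumor_plateau = 50),
               "passive-uptake")
})

test_that("hematology generator reproduces programmed nadir and recovery", {
  sp <- heme_sim_spec(cv = 0, seed = 6)
  hm <- gen_hematology(sp)
  # zero-dose arm stays exactly at baseline
  veh <- hm[hm$group == "vehicle", ]
  expect_true(all(veh$platelets_1e9_per_l == 1000))
  expect_true(all(veh$rbc_1e12_per_l == 9))
  sm <- hematology_summary(hm)
  hi <- sm[sm$group == "ttc600", ]
  plat <- hi[hi$lineage == "platelets_1e9_per_l", ]
  # programmed nadir day 12 depth 0.5, sampled every 14 d
  expect_lte(abs(plat$nadir_day - 12), 14)
  expect_lte(abs(plat$nadir_fraction - 0.5), 0.05)
  expect_lte(abs(plat$recovery_day - 26), 14)
  wbc <- hi[hi$lineage == "wbc_1e9_per_l", ]
  expect_lte(abs(wbc$recovery_day - 39), 14)
  # red blood cells are unaffected by design
  rbc <- hi[hi$lineage == "rbc_1e12_per_l", ]
  expect_identical(rbc$status, "no suppression")
})
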