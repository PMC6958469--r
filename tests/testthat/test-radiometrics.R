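test_that("decay correction inverts forward decay and doubles per half-life", {
  expect_equal(decay_correct(123, 0, th227), 123)
  expect_equal(decay_correct(1, 18.7 * 24, th227), 2)
  expect_equal(decay_correct(1, 336, th227), 2^(14 / 18.7), tolerance = 1e-12)
  t <- c(0, 1, 17, 336, 5000)
  expect_equal(decay_correct(forward_decay(7.7, t, th227), t, th227),
               rep(7.7, length(t)), tolerance = 1e-12)
  expect_error(decay_correct(1, -5, th227), "non-negative")
})

test_that("%IA/g combines decay correction, injected activity, and mass", {
  expect_equal(percent_ia_per_gram(1000, 0, 1, 1000, th227), 100)
  expect_equal(percent_ia_per_gram(500, 0, 2, 1000, th227), 25)
  # 10% of injected activity, uncorrected, in 1 g at 336 h
  expect_equal(percent_ia_per_gram(100, 336, 1, 1000, th227),
               10 * 2^(14 / 18.7), tolerance = 1e-12)
  # linear in activity, inverse-linear in mass
  base <- percent_ia_per_gram(50, 72, 0.5, 1000, th227)
  expect_equal(percent_ia_per_gram(150, 72, 0.5, 1000, th227), 3 * base)
  expect_equal(percent_ia_per_gram(50, 72, 1.5, 1000, th227), base / 3)
  expect_error(percent_ia_per_gram(50, 72, 0, 1000, th227), "mass")
})

test_that("tumor-to-blood ratio handles standard and degenerate inputs", {
  s <- data.frame(organ = c("tumor", "blood"), time_h = 336,
                  mean_pct_ia_g = c(10, 5))
  expect_equal(tumor_to_blood(s, 336)$ratio, 2)
  s$mean_pct_ia_g <- c(4, 4)
  expect_equal(tumor_to_blood(s, 336)$ratio, 1)
  s$mean_pct_ia_g <- c(4, 0)
  out <- tumor_to_blood(s, 336)
  expect_true(is.na(out$ratio))
  expect_match(out$status, "zero")
})

test_that("specific activity converts dose ratios to kBq per microgram", {
  expect_equal(specific_activity(300, 0.14), 300 / 0.14 / 1000)
  expect_equal(round(specific_activity(300, 0.14), 1), 2.1)
  expect_equal(specific_activity(100, 0.1), 1.0)
  # direct division at the highest activity dose (unrounded)
  expect_equal(specific_activity(600, 0.14), 4.285714, tolerance = 1e-6)
  expect_error(specific_activity(300, 0), "positive")
})

test_that("activity-to-molar conversion follows N = A / lambda", {
  expect_equal(activity_to_molar(0, th227), 0)
  lam_s <- log(2) / (18.7 * 86400)
  expect_equal(activity_to_molar(1, th227) * 6.02214076e23, 1 / lam_s)
  expect_equal(1 / lam_s, 2330934, tolerance = 1e-6)
  # linear in activity; doubling half-life doubles molarity
  expect_equal(activity_to_molar(44, th227), 2 * activity_to_molar(22, th227))
  th2 <- nuclide("slow", 2 * 18.7, "days")
  expect_equal(activity_to_molar(1, th2), 2 * activity_to_molar(1, th227))
  expect_equal(kbq_per_ml_to_pm(22, th227), 85.1533, tolerance = 1e-5)
})

test_that("Bateman ingrowth matches its closed-form landmarks", {
  lp <- log(2) / 18.7; ld <- log(2) / 11.43  # per day
  expect_equal(bateman_ingrowth(1000, 0, th227, ra223), 0)
  # transient equilibrium: activity ratio -> lambda_d / (lambda_d - lambda_p)
  ratio_at <- function(t_d)
    bateman_ingrowth(1, t_d * 24, th227, ra223) /
      forward_decay(1, t_d * 24, th227)
  # approach to equilibrium follows 1 - exp(-(ld - lp) t) exactly
  expect_equal(ratio_at(100),
               ld / (ld - lp) * (1 - exp(-(ld - lp) * 100)),
               tolerance = 1e-12)
  expect_equal(ratio_at(300), ld / (ld - lp), tolerance = 0.01)
  # peak ingrowth at ln(ld/lp) / (ld - lp) ~ 20.9 d
  peak <- optimize(function(t) bateman_ingrowth(1, t * 24, th227, ra223),
                   c(1, 100), maximum = TRUE)$maximum
  expect_equal(peak, log(ld / lp) / (ld - lp), tolerance = 1e-4)
  expect_equal(peak, 20.88, tolerance = 0.005)
})

test_that("Bateman daughter activity is non-negative, unimodal, monotone in ratio", {
  t <- seq(0, 200 * 24, by = 6)
  a <- bateman_ingrowth(1, t, th227, ra223)
  expect_true(all(a >= 0))
  peaks <- sum(diff(sign(diff(a))) < 0)
  expect_identical(peaks, 1L)
  ratio <- a[-1] / forward_decay(1, t[-1], th227)
  expect_true(all(diff(ratio) > -1e-12))
})

test_that("equal parent and daughter decay constants use the limiting form", {
  n1 <- nuclide("x", 10, "days")
  n2 <- nuclide("y", 10, "days")
  lam <- log(2) / (10 * 24)
  t <- c(24, 120, 480)
  expect_equal(bateman_ingrowth(5, t, n1, n2), 5 * lam * t * exp(-lam * t))
  # general form converges to the limit as half-lives approach each other
  n3 <- nuclide("z", 10 * (1 + 1e-7), "days")
  expect_equal(bateman_ingrowth(5, t, n1, n3),
               5 * lam * t * exp(-lam * t), tolerance = 1e-5)
})

test_that("the nuclide registry ships Th-227 and Ra-223 and accepts overrides", {
  reg <- nuclide_registry()
  expect_equal(reg[["Th-227"]]$half_life_h, 18.7 * 24)
  expect_equal(reg[["Ra-223"]]$half_life_h, 11.43 * 24)
  reg2 <- nuclide_registry("Ra-223" = nuclide("Ra-223", 11.4354, "days"))
  expect_equal(reg2[["Ra-223"]]$half_life_h, 11.4354 * 24)
})
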