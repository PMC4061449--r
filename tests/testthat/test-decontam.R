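test_that("standard-curve fitting recovers slope, r-squared and efficiency", {
  # noiseless perfect-efficiency series: slope -1/log10(2)
  std <- data.frame(quantity = 10^(0:3), cq = 30 - (0:3) / log10(2))
  cv <- fit_standard_curve(std)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv$efficiency, 1, tolerance = 1e-3)

  # two-point hand regression
  cv2 <- fit_standard_curve(data.frame(quantity = c(1, 100),
                                       cq = c(30, 23.36)))
  expect_equal(cv2$slope, -3.32, tolerance = 1e-9)
  expect_equal(cv2$intercept, 30, tolerance = 1e-9)
  expect_equal(cv2$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_standard_curve(data.frame(quantity = rep(10, 3),
                                             cq = c(25, 25.1, 24.9))),
               "unfittable")
  expect_error(fit_standard_curve(data.frame(quantity = c(-1, 10),
                                             cq = c(30, 25))), "positive")
})

test_that("quantify inverts the curve and censors at the LOD", {
  cv <- fit_standard_curve(data.frame(quantity = c(1, 10, 100),
                                      cq = c(30, 26.6781, 23.3562)))
  q <- quantify(cv$intercept, cv, lod = 0.1)
  expect_equal(q$mass, 1, tolerance = 1e-9)
  expect_false(q$censored)

  # computed mass below LOD -> censored with the LOD as bound
  low_cq <- cv$intercept + cv$slope * log10(0.1)
  q2 <- quantify(low_cq, cv, lod = 0.35)
  expect_true(q2$censored)
  expect_true(is.na(q2$mass))
  expect_equal(q2$lod, 0.35)

  # no amplification -> censored
  expect_true(quantify(NA_real_, cv, lod = 0.35)$censored)
})

test_that("round trip through the fitted line is the identity", {
  cfg <- sim_config(seed = 2, qpcr_efficiency = 0.85, qpcr_intercept = 31)
  cv <- fit_standard_curve(simulate_qpcr(10^seq(-1, 4), cfg, noise_sd = 0))
  masses <- c(0.5, 3, 47, 1234)
  cq <- cv$intercept + cv$slope * log10(masses)
  q <- quantify(cq, cv, lod = 1e-6)
  expect_equal(q$mass, masses, tolerance = 1e-9)
})

test_that("censoring is monotone in the LOD", {
  cv <- fit_standard_curve(data.frame(quantity = c(1, 100),
                                      cq = c(30, 23.36)))
  cqs <- seq(20, 45, by = 2.5)
  lo <- quantify(cqs, cv, lod = 0.1)$censored
  hi <- quantify(cqs, cv, lod = 10)$censored
  expect_true(all(hi[lo]))  # censored at low LOD stays censored at high LOD
})

test_that("fully censored treatments give untreated/LOD lower bounds", {
  tips <- quant_result(rep(NA_real_, 15), lod = 0.350)
  fr <- fold_reduction(parse_mass("21 ng"), tips)
  expect_equal(fr$mean_based_bound, 6e4)
  expect_true(fr$is_lower_bound)

  tubes <- quant_result(rep(NA_real_, 15), lod = 0.72)
  fr2 <- fold_reduction(parse_mass(c("79 ng", "101 ng")), tubes)
  expect_gte(fr2$min_based_bound, 1e5)
  expect_lte(fr2$min_based_bound, fr2$mean_based_bound)
})

test_that("uncensored treatments give a point estimate, not a bound", {
  treated <- quant_result(c(10, 10), lod = 0.1)
  fr <- fold_reduction(c(10, 10), treated)
  expect_equal(fr$mean_based_bound, 1)
  expect_false(fr$is_lower_bound)
})

test_that("fold-reduction bounds scale with mass and inversely with LOD", {
  base <- fold_reduction(1000, quant_result(NA_real_, lod = 0.5))
  x2 <- fold_reduction(2000, quant_result(NA_real_, lod = 0.5))
  half_lod <- fold_reduction(1000, quant_result(NA_real_, lod = 0.25))
  expect_equal(x2$mean_based_bound, 2 * base$mean_based_bound)
  expect_equal(half_lod$mean_based_bound, 2 * base$mean_based_bound)
})

test_that("mixed LODs across treated replicates are rejected", {
  mixed <- rbind(quant_result(NA_real_, lod = 0.35),
                 quant_result(NA_real_, lod = 0.72))
  class(mixed) <- c("quant_result", "data.frame")
  expect_error(fold_reduction(100, mixed), "mixed LODs")
})

test_that("amplification metrics compute fold and template fraction", {
  m <- amplification_metrics(1, parse_mass("37 ng"), parse_mass("10.9 ug"))
  expect_equal(m$fold_amplification, 3.7e4)
  expect_equal(m$template_fraction, 100 * 37e3 / 10.9e6)
  expect_lt(m$template_fraction, 1)

  full <- amplification_metrics(1, 500, 500)
  expect_equal(full$template_fraction, 100)
  expect_error(amplification_metrics(1, 10, 5), "exceed")
  expect_error(amplification_metrics(-1, 10, 20), "positive")
})

test_that("mass suffixes are normalized to picograms", {
  expect_equal(parse_mass(c("1 fg", "1 pg", "1 ng", "1 ug")),
               c(1e-3, 1, 1e3, 1e6))
  expect_equal(parse_mass("0.350pg"), 0.35)
  expect_equal(parse_mass(21), 21)
  expect_error(parse_mass("10 stone"), "cannot parse")
})
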