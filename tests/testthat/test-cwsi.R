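# Frozen oracle values computed from the closed form
# es(Ta) = 0.61 * exp(17.27 * Ta / (Ta + 237.3)):
#   es(25) = 0.61 * exp(431.75/262.3)  = 3.16369...
#   es(27) = 0.61 * exp(466.29/264.3)  = 3.56093...
ES25 <- 0.61 * exp(17.27 * 25 / (25 + 237.3))
ES27 <- 0.61 * exp(17.27 * 27 / (27 + 237.3))

test_that("saturation vapor pressure matches the closed form and is monotone", {
  expect_equal(saturation_vapor_pressure(0), 0.61)
  expect_equal(saturation_vapor_pressure(25), ES25)
  expect_equal(round(saturation_vapor_pressure(25), 4), 3.1636)
  ta <- seq(-20, 50, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(ta)) > 0))
})

test_that("VPD saturates at RH = 100, equals es at RH = 0, and halves at RH = 50", {
  expect_equal(vpd(c(0, 25, 40), 100), c(0, 0, 0))
  expect_equal(vpd(25, 0), ES25)
  expect_equal(vpd(25, 50), ES25 / 2)
  expect_equal(round(vpd(25, 50), 4), 1.5818)
  expect_error(vpd(25, 120), class = "ricelwc_error_validation")
})

test_that("VPG follows the Idso convention with a switchable sign", {
  expect_equal(vpg(25, 0), 0)
  expect_equal(vpg(25, 2), ES25 - ES27)
  expect_lt(vpg(25, 2), 0)
  ta <- seq(0, 45, by = 1)
  expect_true(all(sign(vpg(ta, 2)) == -1))
  expect_true(all(sign(vpg(ta, -2)) == 1))
  expect_equal(vpg(25, 2, sign = -1), -(ES25 - ES27))
})

test_that("baseline fit recovers a noise-free planted line exactly", {
  mc <- simulate_baseline_hours(n = 40, A = 2, B = -2, noise_sd = 0, seed = 3)
  bl <- fit_cwsi_baseline(mc)
  expect_equal(bl$A, 2, tolerance = 1e-9)
  expect_equal(bl$B, -2, tolerance = 1e-9)
  expect_equal(bl$r2_fit, 1, tolerance = 1e-9)
  # two points interpolate perfectly
  mc2 <- tibble::tibble(plot_id = "p", treatment = "CK", hour = c(11, 12),
                        Ta = c(25, 30), RH = c(60, 50))
  mc2$Tc <- mc2$Ta + 1.5 - 1.8 * vpd(mc2$Ta, mc2$RH)
  bl2 <- fit_cwsi_baseline(mc2)
  expect_equal(bl2$A, 1.5, tolerance = 1e-9)
  expect_equal(bl2$B, -1.8, tolerance = 1e-9)
  expect_equal(bl2$r2_fit, 1, tolerance = 1e-9)
})

test_that("baseline fit rejects rank-deficient and empty inputs", {
  mc <- tibble::tibble(plot_id = "p", treatment = "CK", hour = 12,
                       Ta = rep(25, 5), RH = rep(60, 5), Tc = rnorm(5, 26))
  expect_error(fit_cwsi_baseline(mc), class = "ricelwc_error_rank")
  expect_error(fit_cwsi_baseline(mc[0, ]), class = "ricelwc_error_validation")
})

test_that("CWSI hits its analytic limits and is linear in Tc", {
  bl <- structure(list(A = 2, B = -2), class = "lwc_baseline")
  ta <- 25; rh <- 60
  tmin <- 2 - 2 * vpd(ta, rh)
  tmax <- 2 - 2 * vpg(ta, 2)
  expect_equal(cwsi(ta + tmin, ta, rh, bl)$CWSI, 0)
  expect_equal(cwsi(ta + tmax, ta, rh, bl)$CWSI, 1)
  expect_equal(cwsi(ta + (tmin + tmax) / 2, ta, rh, bl)$CWSI, 0.5)
  # strictly increasing in Tc
  vals <- cwsi(seq(20, 35, by = 0.5), ta, rh, bl)$CWSI
  expect_true(all(diff(vals) > 0))
  # out-of-envelope values flagged, not clamped
  res <- cwsi(ta + tmax + 1, ta, rh, bl)
  expect_gt(res$CWSI, 1)
  expect_true(res$out_of_envelope)
})

test_that("a degenerate envelope raises an informative error", {
  bl_bad <- structure(list(A = 2, B = 2), class = "lwc_baseline")
  expect_error(cwsi(26, 25, 60, bl_bad), class = "ricelwc_error_envelope")
})

test_that("window-mean CWSI equals an explicit per-hour loop", {
  camp <- simulate_campaign(simulation_design(n_reps = 1), seed = 11)
  bl <- fit_cwsi_baseline(camp$microclimate)
  agg <- summarise_cwsi(camp$microclimate, bl)
  mc <- camp$microclimate
  one <- agg[5, ]
  rows <- mc[mc$plot_id == one$plot_id & mc$stage == one$stage &
               mc$hour >= 10 & mc$hour <= 14, ]
  manual <- mean(vapply(seq_len(nrow(rows)), function(i) {
    cwsi(rows$Tc[i], rows$Ta[i], rows$RH[i], bl)$CWSI
  }, numeric(1)))
  expect_equal(one$CWSI, manual)
  # constant conditions: mean equals the single-hour value
  mc_const <- tibble::tibble(plot_id = "p", hour = 10:14, Ta = 28,
                             RH = 55, Tc = 29)
  expect_equal(summarise_cwsi(mc_const, bl)$CWSI,
               cwsi(29, 28, 55, bl)$CWSI)
})

test_that("stress ordering and the no-stress degeneracy hold on campaigns", {
  camp <- simulate_campaign(seed = 5)
  bl <- fit_cwsi_baseline(camp$microclimate)
  agg <- summarise_cwsi(camp$microclimate, bl)
  agg <- dplyr::inner_join(
    agg, dplyr::distinct(camp$physiology[c("plot_id", "year", "stage",
                                           "treatment")]),
    by = c("plot_id", "year", "stage"))
  m <- tapply(agg$CWSI, agg$treatment, mean)
  expect_gt(m[["SADW"]], m[["MADW"]])
  expect_gt(m[["MADW"]], m[["CK"]])
  # with no planted stress the index centres on zero everywhere
  d0 <- simulation_design(cwsi_stage_means = c(0, 0, 0, 0), n_reps = 3)
  camp0 <- simulate_campaign(d0, seed = 6)
  bl0 <- fit_cwsi_baseline(camp0$microclimate)
  agg0 <- summarise_cwsi(camp0$microclimate, bl0)
  expect_lt(abs(mean(agg0$CWSI)), 0.05)
})
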