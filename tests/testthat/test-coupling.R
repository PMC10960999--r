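test_that("a planted exact stage line is recovered to numerical precision", {
  d <- tibble::tibble(ND = seq(0.05, 0.25, length.out = 10))
  d$LWC <- 1.49 * d$ND + 0.57
  fit <- fit_stage_line(d, stage = "flowering")
  expect_equal(fit$a, 1.49, tolerance = 1e-9)
  expect_equal(fit$b, 0.57, tolerance = 1e-9)
  expect_equal(fit$r2_fit, 1, tolerance = 1e-12)
  v <- fit_stage_line(d[1:7, ], validation = d[8:10, ])
  expect_equal(v$r2_pred, 1, tolerance = 1e-9)
  expect_equal(v$rmse, 0, tolerance = 1e-9)
  expect_error(fit_stage_line(dplyr::mutate(d, ND = 0.1)),
               class = "ricelwc_error_rank")
  expect_error(fit_stage_line(d[1:2, ]), class = "ricelwc_error_validation")
})

test_that("validation R2 tracks fit R2 on same-distribution data", {
  set.seed(42)
  deltas <- replicate(30, {
    n <- 120
    nd <- runif(n, 0.05, 0.25)
    d <- tibble::tibble(ND = nd, LWC = 0.57 + 1.49 * nd + rnorm(n, 0, 0.02))
    f <- fit_stage_line(d[1:60, ], validation = d[61:120, ])
    f$r2_pred - f$r2_fit
  })
  expect_lt(mean(abs(deltas)), 0.1)
})

test_that("quadratic slope/intercept analysis fits exact and saturated cases", {
  lines3 <- tibble::tibble(stage = c("s1", "s2", "s3"),
                           a = c(1, 4, 9), b = c(2, 3, 5))
  covs3 <- tibble::tibble(stage = c("s1", "s2", "s3"), X = c(1, 2, 3))
  q <- slope_intercept_analysis(lines3, covs3)
  qa <- q[q$target == "slope_a" & q$covariate == "X", ]
  expect_equal(c(qa$c0, qa$c1, qa$c2), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(q$r2, rep(1, 2), tolerance = 1e-9) # 3 points saturate
  expect_error(slope_intercept_analysis(lines3[1:2, ], covs3),
               class = "ricelwc_error_validation")
})

test_that("the campaign's planted quadratic curvature sign is recovered", {
  rep <- suppressMessages(
    run_campaign_analysis(seed = 3, until = "coupling", band_step = 3))
  tr <- truth_report(simulate_campaign(seed = 3))
  q <- rep$quadratics
  c2_a <- q$c2[q$target == "slope_a" & q$covariate == "CWSI"]
  c2_b <- q$c2[q$target == "intercept_b" & q$covariate == "FvFm"]
  expect_equal(sign(c2_a), sign(tr$slope_quad[3]))
  expect_equal(sign(c2_b), sign(tr$intercept_quad[3]))
})

test_that("a coupled model fitted on its generating equation reproduces it", {
  d <- simulate_coupled_data(noise_sd = 0, seed = 1)
  cm <- fit_coupled(d, split = year_split(2022))
  expect_equal(unname(cm$coefficients),
               c(0.57, 1.49, -0.08), tolerance = 1e-9)
  expect_equal(cm$n_train, 55)
  expect_equal(cm$n_valid, 36)
  # evaluating the printed equation at ND = 0.2, CWSI = 0.5
  pred <- predict(cm$fit, newdata = tibble::tibble(ND = 0.2, CWSI = 0.5))
  expect_equal(unname(pred), 1.49 * 0.2 - 0.08 * 0.5 + 0.57) # 0.828
  expect_equal(unname(pred), 0.828)
})

test_that("coefficient CIs cover the planted values across seeds", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_coupled_data(noise_sd = 0.01, seed = s)
    cm <- fit_coupled(d, split = year_split(2022))
    ci <- confint(cm$fit)
    all(ci[, 1] <= c(0.57, 1.49, -0.08) & c(0.57, 1.49, -0.08) <= ci[, 2])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a covariate with zero planted effect has a CI covering zero", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_coupled_data(coefs = c(b0 = 0.57, nd = 1.49, cwsi = 0),
                               noise_sd = 0.01, seed = 100 + s)
    cm <- fit_coupled(d, split = year_split(2022))
    ci <- confint(cm$fit)["CWSI", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("year split demands two years and the improvement table is exact", {
  d <- simulate_coupled_data(seed = 2)
  expect_error(fit_coupled(d[d$year == 2022, ], split = year_split(2022)),
               class = "ricelwc_error_split")
  sl <- fit_stage_line(d, validation = year_split(2022))
  cm <- fit_coupled(d, split = year_split(2022))
  tab <- compare_models(sl, cm)
  expect_equal(tab$delta_pred, cm$prediction_r2 - sl$r2_pred)
  expect_equal(tab$rel_model, cm$model_r2 / sl$r2_fit - 1)
  # mismatched partitions are rejected
  cm2 <- fit_coupled(d[-1, ], split = year_split(2022))
  expect_error(compare_models(sl, cm2), class = "ricelwc_error_validation")
})

test_that("coupled prediction beats ND-only when the covariate carries signal", {
  deltas <- vapply(1:8, function(s) {
    camp <- simulate_campaign(seed = 300 + s)
    phys <- derive_physiology(camp$physiology)
    bl <- fit_cwsi_baseline(camp$microclimate)
    cw <- summarise_cwsi(camp$microclimate, bl)
    obs <- merge_observations(phys, cw)
    vi <- classic_indices(camp$spectra)
    obs <- dplyr::inner_join(obs, vi[c("plot_id", "year", "stage", "ND")],
                             by = c("plot_id", "year", "stage"))
    obs <- obs[obs$stage == "flowering", ]
    sl <- fit_stage_line(obs, validation = year_split(2022))
    cm <- fit_coupled(obs, split = year_split(2022))
    cm$prediction_r2 - sl$r2_pred
  }, numeric(1))
  expect_true(all(deltas > 0))
})
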