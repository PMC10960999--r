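test_that("a planted exact linear relation is found with R2 = 1", {
  set.seed(1)
  sp <- make_toy_spectra(n = 5, bands = c(500, 600, 700, 800), seed = 1)
  nd <- normalized_difference(sp, 600, 800)
  lwc <- 0.7 + 0.3 * nd
  res <- scan_band_pairs(sp, lwc)
  expect_equal(res$best_pair, c(600, 800))
  expect_equal(res$best_r2, 1, tolerance = 1e-12)
  expect_equal(res$best_rmse, 0, tolerance = 1e-8)
})

test_that("the vectorized scan equals a naive double-loop oracle cell-for-cell", {
  set.seed(2)
  bands <- seq(400, 590, by = 10)
  sp <- make_toy_spectra(n = 30, bands = bands, seed = 2, meta = FALSE)
  lwc <- runif(30, 0.6, 0.8)
  res <- scan_band_pairs(sp, lwc)
  oracle <- brute_force_scan(as.matrix(sp), bands, lwc)
  expect_equal(res$r2, oracle$r2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$rmse, oracle$rmse, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scan matrices are exactly swap-symmetric with a masked diagonal", {
  sp <- make_toy_spectra(n = 8, bands = seq(500, 570, 10), seed = 5,
                         meta = FALSE)
  lwc <- runif(8, 0.6, 0.8)
  res <- scan_band_pairs(sp, lwc)
  expect_identical(res$r2, t(res$r2))
  expect_identical(res$rmse, t(res$rmse))
  expect_true(all(is.na(diag(res$r2))))
})

test_that("every cell equals the squared Pearson correlation of ND with LWC", {
  sp <- make_toy_spectra(n = 12, bands = c(450, 500, 550, 600), seed = 6,
                         meta = FALSE)
  lwc <- runif(12, 0.6, 0.8)
  res <- scan_band_pairs(sp, lwc)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      nd <- normalized_difference(sp, res$wavelengths[i],
                                  res$wavelengths[j])
      expect_equal(res$r2[i, j], cor(nd, lwc)^2, tolerance = 1e-12)
    }
  }
})

test_that("ties break toward the lexicographically smaller pair", {
  sp <- tibble::tibble(R500 = c(0.2, 0.3, 0.4, 0.5),
                       R600 = c(0.4, 0.35, 0.3, 0.25))
  sp$R700 <- sp$R600 # identical band duplicates every (x, R600) cell
  nd <- normalized_difference(sp, 500, 600)
  res <- scan_band_pairs(sp, 0.7 + 0.2 * nd)
  expect_equal(res$best_pair, c(500, 600))
})

test_that("constant-ND cells are masked and tiny samples rejected", {
  sp <- tibble::tibble(R500 = rep(0.4, 5), R600 = rep(0.4, 5),
                       R700 = runif(5, 0.2, 0.3))
  expect_message(res <- scan_band_pairs(sp, runif(5, 0.6, 0.8)), "masked")
  expect_true(is.na(res$r2["500", "600"]))
  expect_error(scan_band_pairs(sp[1:2, ], c(0.6, 0.7)),
               class = "ricelwc_error_validation")
})

test_that("full-grid recovery finds the planted pair (3-seed spot check)", {
  for (s in 1:3) {
    camp <- simulate_campaign(seed = s)
    phys <- derive_physiology(camp$physiology)
    sp <- dplyr::inner_join(camp$spectra,
                            phys[c("plot_id", "year", "stage", "LWC")],
                            by = c("plot_id", "year", "stage"))
    sp <- sp[sp$stage == "flowering", ]
    res <- scan_band_pairs(sp[setdiff(names(sp), "LWC")], sp$LWC,
                           stage = "flowering", step = 3)
    expect_lte(abs(res$best_pair[1] - 1287), 25)
    expect_lte(abs(res$best_pair[2] - 1673), 25)
  }
})

test_that("stage table cells match independently refit simple regressions", {
  camp <- simulate_campaign(simulation_design(n_reps = 2), seed = 4)
  phys <- derive_physiology(camp$physiology)
  vi <- classic_indices(camp$spectra)
  d <- dplyr::inner_join(vi, phys[c("plot_id", "year", "stage", "LWC")],
                         by = c("plot_id", "year", "stage"))
  tab <- index_stage_table(d)
  for (k in sample(nrow(tab), 5)) {
    dd <- d[d$stage == tab$stage[k], ]
    fit <- lm(dd$LWC ~ dd[[tab$index[k]]])
    expect_equal(tab$r2[k], summary(fit)$r.squared, tolerance = 1e-12)
  }
  # a noise-free planted relation gives ND cells of exactly 1
  d0 <- simulation_design(reflectance_sd = 0, nd_noise_frac = 0,
                          n_reps = 2)
  camp0 <- simulate_campaign(d0, seed = 4)
  phys0 <- derive_physiology(camp0$physiology)
  vi0 <- classic_indices(camp0$spectra)
  dd0 <- dplyr::inner_join(vi0, phys0[c("plot_id", "year", "stage", "LWC")],
                           by = c("plot_id", "year", "stage"))
  tab0 <- index_stage_table(dd0, indices = "ND")
  expect_equal(tab0$r2, rep(1, 4), tolerance = 1e-9)
})

test_that("an uncorrelated index stays near zero R2 and mostly unflagged", {
  set.seed(10)
  rejections <- replicate(200, {
    d <- tibble::tibble(stage = "booting", X = rnorm(30),
                        LWC = runif(30, 0.6, 0.8))
    tab <- index_stage_table(d, indices = "X")
    c(tab$r2, tab$p_value < 0.05)
  })
  expect_lt(mean(rejections[1, ]), 0.1)       # mean null R2 ~ 1/(n-1)
  expect_lt(mean(rejections[2, ]), 0.12)      # type-I rate near nominal
  expect_gt(mean(rejections[2, ]), 0.005)
})

test_that("scan matrices round-trip through their text files", {
  sp <- make_toy_spectra(n = 6, bands = seq(500, 550, 10), seed = 9,
                         meta = FALSE)
  res <- scan_band_pairs(sp, runif(6, 0.6, 0.8), stage = "booting")
  dir <- withr::local_tempdir()
  write_band_search(res, dir)
  m <- read_band_matrix(file.path(dir, "r2_matrix.tsv"))
  expect_equal(unname(m), unname(res$r2), tolerance = 1e-12)
  bp <- jsonlite::read_json(file.path(dir, "best_pair.json"),
                            simplifyVector = TRUE)
  expect_equal(bp$best_pair, res$best_pair)
})
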