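# Synthetic field-campaign generator. Emulates the statistical structure
# the analysis assumes: treatment-graded LWC populations, water-absorption
# reflectance features that make one near-infrared band pair maximally
# LWC-sensitive, a canopy-temperature stress signal riding on a planted
# non-water-stressed baseline, and covariates tied to LWC with
# closed-form noise variances that hit target correlations. Everything
# planted is returned in a truth record for recovery testing.

#' Simulation design for a synthetic field campaign
#'
#' Collects every planted parameter of the generator. Defaults encode
#' the study conditions the analysis targets: three irrigation regimes
#' (CK > MADW > SADW in leaf water content, overall range about
#' 0.61-0.79), four growth stages, four cultivars over two years, a
#' midday (10:00-14:00) hourly microclimate window, a planted sensitive
#' band pair (1287, 1673) nm, and covariate-LWC correlations inside the
#' reported field ranges (Fv/Fm 0.56-0.71, SPAD 0.53-0.67, CWSI
#' -0.60..-0.85, the last emerging from the stress model rather than
#' being imposed).
#'
#' The per-stage slope `a` and intercept `b` of the planted LWC ~ ND
#' relation are quadratic functions of the planted stage-mean CWSI and
#' stage-mean Fv/Fm respectively (`slope_quad`, `intercept_quad`), so
#' the stage-wise slope/intercept analysis has a known truth.
#'
#' @param years Campaign years (labels used by the year-split rule).
#' @param cultivars Cultivar labels.
#' @param treatments Treatment labels, ordered wettest first.
#' @param n_reps Replicate plots per year x cultivar x treatment cell.
#' @param stages Growth-stage labels in chronological order.
#' @param lwc_means Treatment x stage matrix of latent LWC means.
#' @param lwc_sd Within-cell latent LWC standard deviation.
#' @param hours Hours of day with microclimate records.
#' @param A_true,B_true Planted baseline intercept (deg C) and slope
#'   (deg C per kPa).
#' @param stress_sd Per-plot stress heterogeneity (normalized-LWC units).
#' @param tc_sd Hourly canopy-temperature noise, deg C.
#' @param cwsi_stage_means Planted stage-mean CWSI targets driving the
#'   stage stress gains.
#' @param fvfm_stage_means Planted stage-mean Fv/Fm.
#' @param band_pair Planted sensitive band pair (lambda_a, lambda_b), nm.
#' @param reflectance_sd Per-band i.i.d. reflectance noise.
#' @param nd_noise_frac Plot-level jitter of the planted ND, as a
#'   fraction of the within-stage LWC spread mapped through the slope.
#' @param slope_quad,intercept_quad Quadratic coefficients `c(c0, c1,
#'   c2)` mapping stage-mean CWSI to slope a, and stage-mean Fv/Fm to
#'   intercept b.
#' @param covariate_targets Named vector of target Pearson correlations
#'   with LWC for the linear-in-LWC Gaussian covariates.
#' @return An object of class `lwc_design` (a list).
#' @export
simulation_design <- function(
    years = c(2021, 2022),
    cultivars = paste0("CV", 1:4),
    treatments = c("CK", "MADW", "SADW"),
    n_reps = 5,
    stages = c("booting", "flowering", "initial_filling", "middle_filling"),
    lwc_means = rbind(
      CK   = c(0.79, 0.77, 0.75, 0.73),
      MADW = c(0.73, 0.71, 0.69, 0.67),
      SADW = c(0.67, 0.65, 0.63, 0.61)
    ),
    lwc_sd = 0.02,
    hours = 10:14,
    A_true = 2.0,
    B_true = -2.0,
    stress_sd = 0.4,
    tc_sd = 0.3,
    cwsi_stage_means = c(0.22, 0.30, 0.38, 0.46),
    fvfm_stage_means = c(0.82, 0.78, 0.74, 0.70),
    band_pair = c(1287, 1673),
    reflectance_sd = 0.008,
    nd_noise_frac = 0.6,
    slope_quad = c(0.561667, 11.583333, -25),
    intercept_quad = c(-23.975, 66.65, -45),
    covariate_targets = c(SPAD = 0.60, FvFm = 0.63, YII = 0.50,
                          LAI = 0.50, biomass = 0.45, yield = 0.55)) {
  colnames(lwc_means) <- stages
  if (lwc_sd < 0 || reflectance_sd < 0 || tc_sd < 0 || stress_sd < 0) {
    stop_ricelwc("noise scales must be non-negative",
                 class = "ricelwc_error_validation")
  }
  bad <- names(covariate_targets)[abs(covariate_targets) >= 1 |
                                    covariate_targets == 0]
  if (length(bad) > 0) {
    stop_ricelwc(
      sprintf("correlation target for %s is unreachable (must be in (-1, 1), non-zero)",
              paste(bad, collapse = ", ")),
      class = "ricelwc_error_design"
    )
  }
  if (band_pair[1] == band_pair[2] ||
      any(band_pair < 350 | band_pair > 2500)) {
    stop_ricelwc("band_pair must be two distinct wavelengths on the 350-2500 nm grid",
                 class = "ricelwc_error_design")
  }
  structure(
    list(years = years, cultivars = cultivars, treatments = treatments,
         n_reps = n_reps, stages = stages, lwc_means = lwc_means,
         lwc_sd = lwc_sd, hours = hours, A_true = A_true, B_true = B_true,
         stress_sd = stress_sd, tc_sd = tc_sd,
         cwsi_stage_means = cwsi_stage_means,
         fvfm_stage_means = fvfm_stage_means, band_pair = band_pair,
         reflectance_sd = reflectance_sd, nd_noise_frac = nd_noise_frac,
         slope_quad = slope_quad, intercept_quad = intercept_quad,
         covariate_targets = covariate_targets),
    class = "lwc_design"
  )
}

quad_eval <- function(q, x) q[1] + q[2] * x + q[3] * x^2

# Noise standard deviation that makes cor(X, LWC) = r for
# X = mu + gain * (LWC - mean) + eps in the linear-Gaussian model.
corr_noise_sd <- function(gain, sd_l, r) {
  abs(gain) * sd_l * sqrt(1 / r^2 - 1)
}

# Smooth dry-canopy base reflectance over the 1-nm grid (linear
# interpolation through control points typical of green vegetation).
base_reflectance <- function(grid = 350:2500) {
  pts_wl <- c(350, 500, 550, 680, 720, 780, 1300, 1450, 1660, 1700,
              1900, 1940, 2100, 2500)
  pts_r  <- c(0.04, 0.05, 0.09, 0.05, 0.30, 0.45, 0.45, 0.42, 0.40,
              0.40, 0.36, 0.35, 0.30, 0.22)
  stats::approx(pts_wl, pts_r, xout = grid)$y
}

#' Simulate a complete synthetic field campaign
#'
#' Generates the three input tables of the pipeline (wide canopy
#' spectra, hourly microclimate, plot-level physiology/trait table) plus
#' a truth record of every planted parameter.
#'
#' The generative model: (1) latent LWC per plot/stage from
#' treatment-stage means; (2) reflectance as a smooth base curve minus
#' water-absorption troughs near 1450 and 1940 nm whose depths grow with
#' LWC, plus a narrow feature pair at the planted bands constructed so
#' the noise-free ND at `band_pair` equals `(LWC - b_s)/a_s` exactly
#' (stage-specific planted line), plus i.i.d. band noise; (3) hourly
#' canopy temperature `Tc - Ta = A + B * VPD + s_stage * (1 - LWC_norm +
#' eta) + noise`, with `LWC_norm` scaled so well-watered (CK) plots sit
#' on the planted baseline in expectation and `s_stage` scaled so the
#' stage-mean CWSI matches the planted target; (4) covariates linear in
#' LWC with closed-form noise hitting the target correlations,
#' materialised as raw measurables (FW/DW, Fo/Fm, Fs/Fm', SPAD, leaf
#' area D and density rho, biomass, yield).
#'
#' @param design An `lwc_design` from [simulation_design()].
#' @param seed Integer seed; the same seed reproduces the campaign
#'   bit-identically.
#' @return Object of class `lwc_campaign`: a list with tibbles
#'   `spectra`, `microclimate`, `physiology`, the `truth` record and the
#'   `design`.
#' @export
simulate_campaign <- function(design = simulation_design(), seed = 1) {
  stopifnot(inherits(design, "lwc_design"))
  set.seed(seed)
  grid <- 350:2500
  stages <- design$stages
  n_stage <- length(stages)

  # plot frame: one physical plot per year x cultivar x treatment x rep
  plots <- tidyr::expand_grid(
    year = design$years, cultivar = design$cultivars,
    treatment = design$treatments, rep = seq_len(design$n_reps)
  ) %>%
    dplyr::mutate(plot_id = sprintf("%d-%s-%s-%d", .data$year,
                                    .data$cultivar, .data$treatment,
                                    .data$rep))

  # planted stage lines from the quadratic structure
  a_true <- quad_eval(design$slope_quad, design$cwsi_stage_means)
  b_true <- quad_eval(design$intercept_quad, design$fvfm_stage_means)

  obs <- tidyr::expand_grid(plots, stage = stages) %>%
    dplyr::mutate(stage_i = match(.data$stage, stages))
  mu <- design$lwc_means[cbind(match(obs$treatment, rownames(design$lwc_means)),
                               obs$stage_i)]
  obs$LWC_latent <- mu + rnorm(nrow(obs), 0, design$lwc_sd)

  # normalized LWC per stage: CK mean -> 1, SADW mean -> 0
  m_ck <- design$lwc_means[1, obs$stage_i]
  m_sadw <- design$lwc_means[nrow(design$lwc_means), obs$stage_i]
  obs$lwc_norm <- (obs$LWC_latent - m_sadw) / (m_ck - m_sadw)

  # --- microclimate -----------------------------------------------------
  hrs <- design$hours
  ta_det <- 27 + 0.8 * (hrs - hrs[1])
  rh_det <- 70 - 3 * (hrs - hrs[1])
  vpd_det <- vpd(ta_det, rh_det)
  vpg_det <- vpg(ta_det, design$A_true)
  denom_mean <- mean(design$B_true * (vpg_det - vpd_det))
  mean_one_minus_norm <- mean(1 - (design$lwc_means[, 1] - design$lwc_means[3, 1]) /
                                (design$lwc_means[1, 1] - design$lwc_means[3, 1]))
  s_stage <- design$cwsi_stage_means * denom_mean / mean_one_minus_norm

  mc <- tidyr::expand_grid(
    obs[c("plot_id", "year", "treatment", "stage", "stage_i")],
    hour = hrs
  )
  idx <- match(paste(mc$plot_id, mc$stage), paste(obs$plot_id, obs$stage))
  eta <- rnorm(nrow(obs), 0, design$stress_sd)
  h_i <- match(mc$hour, hrs)
  mc$Ta <- ta_det[h_i] + rnorm(nrow(mc), 0, 0.2)
  mc$RH <- pmin(95, pmax(5, rh_det[h_i] + rnorm(nrow(mc), 0, 1)))
  stress <- s_stage[mc$stage_i] *
    (1 - obs$lwc_norm[idx] + eta[idx])
  mc$Tc <- mc$Ta + design$A_true + design$B_true * vpd(mc$Ta, mc$RH) +
    stress + rnorm(nrow(mc), 0, design$tc_sd)
  microclimate <- mc %>%
    dplyr::select("plot_id", "year", "treatment", "stage", "hour",
                  "Tc", "Ta", "RH")

  # --- covariates and raw physiology -----------------------------------
  # realized within-stage LWC spread (population sd), so the closed-form
  # covariate noise hits the target correlation without attenuation
  sd_by_stage <- vapply(seq_len(n_stage), function(i) {
    x <- obs$LWC_latent[obs$stage_i == i]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  sd_l <- sd_by_stage[obs$stage_i]
  mean_l <- vapply(obs$stage_i,
                   function(i) mean(design$lwc_means[, i]), numeric(1))
  tgt <- design$covariate_targets
  lin_cov <- function(mu_s, gain, r) {
    mu_s + gain * (obs$LWC_latent - mean_l) +
      rnorm(nrow(obs), 0, corr_noise_sd(gain, sd_l, r))
  }
  spad_mu <- c(41, 40, 38, 36)[obs$stage_i]
  fvfm_mu <- design$fvfm_stage_means[obs$stage_i]
  yii_mu <- c(0.60, 0.58, 0.54, 0.50)[obs$stage_i]
  lai_mu <- c(5.0, 5.5, 5.2, 4.6)[obs$stage_i]
  bio_mu <- c(7, 9, 12, 14)[obs$stage_i]

  obs$SPAD <- lin_cov(spad_mu, 30, tgt[["SPAD"]])
  obs$FvFm <- pmin(0.95, pmax(0.05, lin_cov(fvfm_mu, 0.8, tgt[["FvFm"]])))
  obs$YII <- pmin(0.95, pmax(0.05, lin_cov(yii_mu, 0.8, tgt[["YII"]])))
  obs$LAI_latent <- pmax(0.2, lin_cov(lai_mu, 8, tgt[["LAI"]]))
  obs$biomass <- pmax(0.5, lin_cov(bio_mu, 30, tgt[["biomass"]]))
  obs$yield <- pmax(0.5, lin_cov(9, 25, tgt[["yield"]]))

  rho <- 1 / (0.300 * 0.133) # 30.0 cm x 13.3 cm spacing, hills per m^2
  FW <- rnorm(nrow(obs), 4, 0.3)
  Fm <- rnorm(nrow(obs), 2000, 80)
  Fm_prime <- rnorm(nrow(obs), 1500, 60)
  physiology <- obs %>%
    dplyr::transmute(
      .data$plot_id, .data$year, .data$cultivar, .data$treatment,
      .data$stage,
      FW = FW, DW = FW * (1 - .data$LWC_latent),
      Fo = Fm * (1 - .data$FvFm), Fm = Fm,
      Fs = Fm_prime * (1 - .data$YII), Fm_prime = Fm_prime,
      SPAD = .data$SPAD,
      D = .data$LAI_latent * 10000 / rho, rho = rho,
      biomass = .data$biomass, yield = .data$yield
    )

  # --- spectra ----------------------------------------------------------
  base <- base_reflectance(grid)
  lam_a <- design$band_pair[1]
  lam_b <- design$band_pair[2]
  g_bump <- exp(-(grid - lam_a)^2 / (2 * 12^2))
  g_nd <- exp(-(grid - lam_b)^2 / (2 * 18^2))
  g_1450 <- exp(-(grid - 1450)^2 / (2 * 45^2))
  g_1940 <- exp(-(grid - 1940)^2 / (2 * 55^2))
  i_a <- match(lam_a, grid)
  i_b <- match(lam_b, grid)

  n_obs <- nrow(obs)
  # latent spectral water signal: LWC plus plot-level jitter shared by
  # every water-driven reflectance feature, so the planted pair (built
  # exactly from W) is the least-noisy channel on the grid
  W <- obs$LWC_latent + rnorm(n_obs, 0, design$nd_noise_frac * sd_l)
  nd_target <- (W - b_true[obs$stage_i]) / a_true[obs$stage_i]
  d1450 <- 0.12 + 0.4 * (W - 0.7) + rnorm(n_obs, 0, 0.04)
  d1940 <- 0.18 + 0.4 * (W - 0.7) + rnorm(n_obs, 0, 0.04)
  # bump gain 0.29 splits the W signal roughly evenly between the two
  # planted bands, so neither band alone rivals the pair's contrast
  bump_amp <- 0.29 * (W - 0.7)

  R <- matrix(0, n_obs, length(grid))
  for (k in seq_len(n_obs)) {
    r <- base + bump_amp[k] * g_bump - d1450[k] * g_1450 -
      d1940[k] * g_1940
    target_b <- r[i_a] * (1 - nd_target[k]) / (1 + nd_target[k])
    r <- r - (r[i_b] - target_b) * g_nd
    R[k, ] <- r
  }
  R <- R + matrix(rnorm(length(R), 0, design$reflectance_sd), nrow = n_obs)
  R[R < 0.001] <- 0.001 # floor: real canopies never reflect exactly zero
  R[R > 1] <- 1
  colnames(R) <- paste0("R", grid)
  spectra <- dplyr::bind_cols(
    obs[c("plot_id", "year", "cultivar", "treatment", "stage")],
    tibble::as_tibble(R)
  )

  truth <- list(
    A_true = design$A_true, B_true = design$B_true,
    band_pair = design$band_pair,
    stage_lines = tibble::tibble(
      stage = stages, a_true = a_true, b_true = b_true,
      cwsi_target = design$cwsi_stage_means,
      fvfm_target = design$fvfm_stage_means,
      stress_gain = s_stage
    ),
    slope_quad = design$slope_quad,
    intercept_quad = design$intercept_quad,
    covariate_targets = design$covariate_targets,
    latent_lwc = obs[c("plot_id", "year", "cultivar", "treatment",
                       "stage", "LWC_latent")],
    seed = seed
  )

  structure(
    list(spectra = spectra, microclimate = microclimate,
         physiology = physiology, truth = truth, design = design),
    class = "lwc_campaign"
  )
}

#' @export
print.lwc_campaign <- function(x, ...) {
  cat(sprintf(
    "Synthetic campaign: %d spectra rows, %d microclimate hours, %d physiology rows (seed %d)\n",
    nrow(x$spectra), nrow(x$microclimate), nrow(x$physiology),
    x$truth$seed))
  invisible(x)
}

#' Structured summary of the planted truth of a campaign
#'
#' @param campaign An `lwc_campaign`.
#' @return A list with the planted baseline (`A_true`, `B_true`), the
#'   planted band pair, the per-stage planted slope/intercept table and
#'   the covariate correlation targets.
#' @export
truth_report <- function(campaign) {
  stopifnot(inherits(campaign, "lwc_campaign"))
  tr <- campaign$truth
  list(
    A_true = tr$A_true, B_true = tr$B_true, band_pair = tr$band_pair,
    stage_lines = tr$stage_lines,
    slope_quad = tr$slope_quad, intercept_quad = tr$intercept_quad,
    covariate_targets = tr$covariate_targets, seed = tr$seed
  )
}

#' Simulate well-watered hourly records on a known baseline
#'
#' Generates `n` midday hours with `Tc - Ta = A + B * VPD + noise`, for
#' baseline-recovery testing.
#'
#' @param n Number of hourly records.
#' @param A,B Planted baseline coefficients.
#' @param noise_sd Canopy-temperature noise, deg C.
#' @param seed Integer seed.
#' @return Microclimate tibble (`plot_id`, `treatment = "CK"`, `hour`,
#'   `Tc`, `Ta`, `RH`).
#' @export
simulate_baseline_hours <- function(n = 200, A = 2.0, B = -2.0,
                                    noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  ta <- runif(n, 24, 34)
  rh <- runif(n, 40, 80)
  tibble::tibble(
    plot_id = "CK-1", treatment = "CK",
    hour = sample(10:14, n, replace = TRUE),
    Ta = ta, RH = rh,
    Tc = ta + A + B * vpd(ta, rh) + rnorm(n, 0, noise_sd)
  )
}

#' Simulate observations from a planted coupled linear model
#'
#' Draws (ND, CWSI) predictors and generates `LWC = b0 + b_nd * ND +
#' b_cwsi * CWSI + eps`, split into a training year and a validation
#' year so the year-split rule is exercised literally.
#'
#' @param n_train,n_valid Sample sizes of the training and validation
#'   years.
#' @param coefs Named vector `c(b0, nd, cwsi)` of planted coefficients.
#' @param noise_sd Residual standard deviation of LWC.
#' @param train_year,valid_year Year labels.
#' @param seed Integer seed.
#' @return Tibble with `year`, `ND`, `CWSI`, `LWC`.
#' @export
simulate_coupled_data <- function(n_train = 55, n_valid = 36,
                                  coefs = c(b0 = 0.57, nd = 1.49,
                                            cwsi = -0.08),
                                  noise_sd = 0.01,
                                  train_year = 2022, valid_year = 2021,
                                  seed = 1) {
  set.seed(seed)
  n <- n_train + n_valid
  nd <- runif(n, 0.05, 0.25)
  cw <- runif(n, 0, 1)
  tibble::tibble(
    year = rep(c(train_year, valid_year), c(n_train, n_valid)),
    ND = nd, CWSI = cw,
    LWC = coefs[["b0"]] + coefs[["nd"]] * nd + coefs[["cwsi"]] * cw +
      rnorm(n, 0, noise_sd)
  )
}

#' Simulate a nonlinear benchmark set with an ND x CWSI interaction
#'
#' Plants an interaction term a linear model cannot express, so tree
#' ensembles have a genuine advantage:
#' `LWC = b0 + b_nd * ND + b_cwsi * CWSI + k * (ND - 0.15) * (CWSI - 0.5)
#' + eps`.
#'
#' @param n Number of observations (default 91, a typical per-stage
#'   sample count).
#' @param interaction Interaction strength `k`.
#' @param noise_sd Residual standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `ND`, `CWSI`, `LWC`.
#' @export
simulate_ml_benchmark <- function(n = 91, interaction = 8,
                                  noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  nd <- runif(n, 0.05, 0.25)
  cw <- runif(n, 0, 1)
  tibble::tibble(
    ND = nd, CWSI = cw,
    LWC = 0.57 + 1.49 * nd - 0.08 * cw +
      interaction * (nd - 0.15) * (cw - 0.5) + rnorm(n, 0, noise_sd)
  )
}
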