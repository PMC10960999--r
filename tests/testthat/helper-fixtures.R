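# Small programmatic fixtures shared across test files.

# A toy wide spectra tibble on an arbitrary (small) grid.
make_toy_spectra <- function(n = 5, bands = c(500, 600, 700, 800),
                             seed = 42, meta = TRUE) {
  set.seed(seed)
  R <- matrix(runif(n * length(bands), 0.1, 0.6), nrow = n)
  colnames(R) <- paste0("R", bands)
  out <- tibble::as_tibble(R)
  if (meta) {
    out <- dplyr::bind_cols(
      tibble::tibble(plot_id = paste0("p", seq_len(n)),
                     stage = "flowering"),
      out)
  }
  out
}

# Full-grid spectra (2151 bands) for a handful of plots; flat base with
# small noise, values safely inside (0, 1).
make_fullgrid_spectra <- function(n = 3, seed = 7) {
  set.seed(seed)
  grid <- 350:2500
  R <- matrix(runif(n * length(grid), 0.2, 0.5), nrow = n)
  colnames(R) <- paste0("R", grid)
  dplyr::bind_cols(
    tibble::tibble(plot_id = paste0("p", seq_len(n)), stage = "booting"),
    tibble::as_tibble(R))
}

# Brute-force two-band scan oracle: naive double loop, per-pair lm().
brute_force_scan <- function(R, wl, y) {
  p <- length(wl)
  r2 <- rmse <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      nd <- (R[, i] - R[, j]) / (R[, i] + R[, j])
      if (sd(nd) == 0) next
      fit <- lm(y ~ nd)
      r2[i, j] <- summary(fit)$r.squared
      rmse[i, j] <- sqrt(mean(resid(fit)^2))
    }
  }
  list(r2 = r2, rmse = rmse)
}
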