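# Exhaustive two-band normalized-difference screening against LWC.
# For every unordered band pair the simple linear regression
# LWC ~ ND(l1, l2) is summarised by R^2 and RMSE; for a single-predictor
# OLS fit R^2 equals the squared Pearson correlation and
# RMSE = sqrt(SStot * (1 - R^2) / n), which lets the whole scan run as
# column-wise correlations against a fixed response. Only the upper
# triangle is computed; the lower triangle is mirrored (swapping the
# bands negates ND, leaving R^2 and RMSE unchanged).

#' Scan all two-band normalized-difference pairs against LWC
#'
#' @param spectra Wide spectra tibble (`R<wavelength>` columns) for the
#'   samples of one stage.
#' @param lwc Numeric LWC vector aligned with the rows of `spectra`.
#' @param stage Optional stage label carried into the result.
#' @param step Grid decimation step in nm (default 1, the full grid).
#' @param bands Optional explicit integer vector of wavelengths to scan
#'   (overrides `step`).
#' @return Object of class `lwc_band_search`: wavelengths, symmetric
#'   `r2` and `rmse` matrices (diagonal and constant-ND cells `NA`),
#'   `best_pair`, `best_r2`, `best_rmse`, `n_samples`. Ties on R^2 break
#'   by smaller RMSE, then lexicographically smaller pair.
#' @export
scan_band_pairs <- function(spectra, lwc, stage = NA_character_,
                            step = 1, bands = NULL) {
  sm <- spectral_matrix(spectra)
  if (length(lwc) != nrow(sm$R)) {
    stop_ricelwc("`lwc` length must match the number of spectra rows",
                 class = "ricelwc_error_validation")
  }
  if (nrow(sm$R) < 3) {
    stop_ricelwc("need at least 3 samples for the band scan",
                 class = "ricelwc_error_validation")
  }
  wl <- sm$wavelengths
  keep <- if (!is.null(bands)) wl %in% bands else
    (wl - wl[1]) %% step == 0
  wl <- wl[keep]
  R <- sm$R[, keep, drop = FALSE]
  p <- length(wl)
  n <- nrow(R)
  y <- lwc
  yc <- y - mean(y)
  ss_tot <- sum(yc^2)
  if (ss_tot == 0) {
    stop_ricelwc("LWC has zero variance", class = "ricelwc_error_validation")
  }

  r2 <- matrix(NA_real_, p, p, dimnames = list(wl, wl))
  n_masked <- 0L
  for (i in seq_len(p - 1)) {
    j <- (i + 1):p
    nd <- (R[, i] - R[, j, drop = FALSE]) / (R[, i] + R[, j, drop = FALSE])
    nd[!is.finite(nd)] <- NA_real_
    ndc <- sweep(nd, 2, colMeans(nd))
    ssx <- colSums(ndc^2)
    ok <- !is.na(ssx) & ssx > 0
    num <- drop(crossprod(ifelse(is.na(ndc), 0, ndc), yc))
    cell <- ifelse(ok, num^2 / (ssx * ss_tot), NA_real_)
    n_masked <- n_masked + sum(!ok)
    r2[i, j] <- cell
    r2[j, i] <- cell
  }
  if (n_masked > 0) {
    inform(sprintf("band scan: %d cell(s) masked (constant ND)", n_masked))
  }
  rmse <- sqrt(pmax(ss_tot * (1 - r2), 0) / n)

  # best pair: max R^2, ties by smaller RMSE then lexicographic order
  ut <- upper.tri(r2)
  cand <- which(ut & !is.na(r2), arr.ind = TRUE)
  o <- order(-r2[cand], rmse[cand], wl[cand[, 1]], wl[cand[, 2]])
  best <- cand[o[1], ]
  structure(
    list(stage = stage, wavelengths = wl, r2 = r2, rmse = rmse,
         best_pair = c(wl[best[1]], wl[best[2]]),
         best_r2 = r2[best[1], best[2]],
         best_rmse = rmse[best[1], best[2]],
         n_samples = n),
    class = "lwc_band_search"
  )
}

#' @export
print.lwc_band_search <- function(x, ...) {
  cat(sprintf(
    "Two-band ND scan (%s): %d bands, n = %d; best pair (%d, %d) with R2 = %.3f, RMSE = %.4f\n",
    ifelse(is.na(x$stage), "all stages", x$stage), length(x$wavelengths),
    x$n_samples, x$best_pair[1], x$best_pair[2], x$best_r2, x$best_rmse))
  invisible(x)
}

#' @export
glance.lwc_band_search <- function(x, ...) {
  tibble::tibble(stage = x$stage, lambda1 = x$best_pair[1],
                 lambda2 = x$best_pair[2], best_r2 = x$best_r2,
                 best_rmse = x$best_rmse, n_samples = x$n_samples)
}

#' @export
tidy.lwc_band_search <- function(x, ...) {
  ut <- upper.tri(x$r2)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    lambda1 = x$wavelengths[idx[, 1]],
    lambda2 = x$wavelengths[idx[, 2]],
    r2 = x$r2[idx], rmse = x$rmse[idx]
  )
}

#' Per-stage comparison of ND and classical indices against LWC
#'
#' For each stage and each index column, fits the simple linear
#' regression `LWC ~ index` and reports R^2 with a significance marker
#' from the regression F test (uncorrected, `*` at 5 percent, `**` at 1
#' percent).
#'
#' @param data Tibble with a `stage` column, index columns and an LWC
#'   column.
#' @param indices Character vector of index column names.
#' @param lwc Name of the LWC column (default `"LWC"`).
#' @return Tibble with `stage`, `index`, `r2`, `p_value`, `signif`.
#' @export
index_stage_table <- function(data, indices = c("ND", "NDVI", "NDII",
                                                "NDWI", "WI", "MSI"),
                              lwc = "LWC") {
  check_columns(data, c("stage", lwc, indices), "index table")
  tidyr::expand_grid(stage = unique(data$stage), index = indices) %>%
    purrr::pmap(function(stage, index) {
      d <- data[data$stage == stage, ]
      fit <- lm(d[[lwc]] ~ d[[index]])
      fs <- summary(fit)$fstatistic
      p <- unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
      tibble::tibble(stage = stage, index = index,
                     r2 = summary(fit)$r.squared, p_value = p,
                     signif = signif_marker(p))
    }) %>%
    dplyr::bind_rows()
}

signif_marker <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Write band-scan matrices to delimited text
#'
#' Writes `r2_matrix.tsv`, `rmse_matrix.tsv` (wavelength-labelled, `NA`
#' for masked cells) and `best_pair.json` into `dir`. The rendered heat
#' map is available through [autoplot.lwc_band_search()].
#'
#' @param result An `lwc_band_search`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_band_search <- function(result, dir) {
  stopifnot(inherits(result, "lwc_band_search"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix <- function(m, path) {
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    names(df) <- paste0("R", result$wavelengths)
    df <- dplyr::bind_cols(tibble::tibble(wavelength = result$wavelengths),
                           df)
    readr::write_tsv(df, path)
  }
  write_matrix(result$r2, file.path(dir, "r2_matrix.tsv"))
  write_matrix(result$rmse, file.path(dir, "rmse_matrix.tsv"))
  jsonlite::write_json(
    list(stage = result$stage, best_pair = result$best_pair,
         best_r2 = result$best_r2, best_rmse = result$best_rmse,
         n_samples = result$n_samples),
    file.path(dir, "best_pair.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a band-scan matrix written by [write_band_search()]
#'
#' @param path Path to `r2_matrix.tsv` or `rmse_matrix.tsv`.
#' @return Numeric matrix with wavelength dimnames.
#' @export
read_band_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  dimnames(m) <- list(df$wavelength, sub("^R", "", colnames(df)[-1]))
  m
}

#' Heat map of a two-band scan
#'
#' R^2 (or RMSE) over all band pairs, with the selected best pair
#' marked. Masked cells are blank.
#'
#' @param object An `lwc_band_search`.
#' @param metric `"r2"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwc_band_search <- function(object, metric = c("r2", "rmse"),
                                     ...) {
  metric <- match.arg(metric)
  m <- object[[metric]]
  idx <- which(!is.na(m), arr.ind = TRUE)
  df <- tibble::tibble(
    lambda1 = object$wavelengths[idx[, 1]],
    lambda2 = object$wavelengths[idx[, 2]],
    value = m[idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda1, .data$lambda2,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = toupper(metric)) +
    ggplot2::annotate("point", x = object$best_pair[1],
                      y = object$best_pair[2], shape = 4, size = 3,
                      colour = "red") +
    ggplot2::labs(
      x = expression(lambda[1] ~ "(nm)"), y = expression(lambda[2] ~ "(nm)"),
      title = sprintf("Two-band ND scan%s; best pair (%d, %d)",
                      ifelse(is.na(object$stage), "",
                             paste0(" - ", object$stage)),
                      object$best_pair[1], object$best_pair[2])) +
    ggplot2::theme_minimal()
}
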