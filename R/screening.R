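# Covariate screening and regression diagnostics: Pearson correlation
# matrices with significance markers, descriptive statistics, outlier
# flags, Shapiro-Wilk normality, collinearity (VIF/tolerance) and the
# Durbin-Watson statistic.

#' Pearson correlation matrix with significance markers
#'
#' Pairwise-complete Pearson correlations among `variables`, with
#' two-sided t-test p-values and uncorrected 5/1 percent markers.
#' Zero-variance variables are masked (NA row/column) and reported.
#'
#' @param data Data frame of observations.
#' @param variables Character vector of numeric column names.
#' @return Object of class `lwc_pcc`: list with matrices `r`, `p`, `n`
#'   and the variable names. `tidy()` returns the long form.
#' @export
pcc_matrix <- function(data, variables) {
  check_columns(data, variables, "observations")
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k,
                        dimnames = list(variables, variables))
  masked <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- data[[variables[i]]]
      y <- data[[variables[j]]]
      ok <- complete.cases(x, y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        if (sum(ok) >= 3 && (sd(x[ok]) == 0 || sd(y[ok]) == 0)) {
          masked <- union(masked, variables[c(i, j)][c(sd(x[ok]) == 0,
                                                       sd(y[ok]) == 0)])
        }
        next
      }
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
      } else {
        ct <- cor.test(x[ok], y[ok])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  if (length(masked) > 0) {
    inform(sprintf("pcc_matrix: zero-variance variable(s) masked: %s",
                   paste(masked, collapse = ", ")))
  }
  structure(list(r = r, p = p, n = n, variables = variables),
            class = "lwc_pcc")
}

#' @export
tidy.lwc_pcc <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[idx[, 1]], var2 = x$variables[idx[, 2]],
    r = x$r[idx], p_value = x$p[idx], n = x$n[idx],
    signif = signif_marker(x$p[idx])
  )
}

#' @export
print.lwc_pcc <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", nrow(x$r), " variables)\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Tile plot of a correlation matrix
#'
#' @param object An `lwc_pcc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwc_pcc <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(df, dplyr::rename(df, var1 = "var2", var2 = "var1"))
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r, .data$signif)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Rank covariates by correlation with LWC across stages
#'
#' Per-stage Pearson r of each covariate with the response is averaged
#' in absolute value across stages; the top-`k` covariates are returned.
#' Ties break alphabetically.
#'
#' @param data Observations with a `stage` column.
#' @param covariates Candidate covariate column names.
#' @param response Response column (default `"LWC"`).
#' @param k How many covariates to keep (default 3).
#' @return Tibble `covariate`, `mean_abs_r`, `mean_r`, `rank`, plus the
#'   per-stage correlations nested in `by_stage`.
#' @export
rank_covariates <- function(data, covariates, response = "LWC", k = 3) {
  check_columns(data, c("stage", response, covariates), "observations")
  per_stage <- data %>%
    dplyr::group_by(.data$stage) %>%
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        covariate = covariates,
        r = vapply(covariates,
                   function(v) cor(d[[response]], d[[v]],
                                   use = "complete.obs"),
                   numeric(1))
      )
    }) %>%
    dplyr::ungroup()
  ranking <- per_stage %>%
    dplyr::group_by(.data$covariate) %>%
    dplyr::summarise(mean_abs_r = mean(abs(.data$r)),
                     mean_r = mean(.data$r), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$mean_abs_r), .data$covariate) %>%
    dplyr::mutate(rank = dplyr::row_number())
  out <- head(ranking, k)
  attr(out, "by_stage") <- per_stage
  out
}

#' Descriptive statistics per variable
#'
#' Max, min, mean, standard deviation (n - 1 denominator) and
#' coefficient of variation CV = SD/mean (masked when the mean is zero).
#'
#' @param data Data frame.
#' @param variables Numeric column names.
#' @return Tibble with one row per variable.
#' @export
descriptive_stats <- function(data, variables) {
  check_columns(data, variables, "observations")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) == 0) {
      stop_ricelwc(sprintf("variable %s has no data", v),
                   class = "ricelwc_error_validation")
    }
    m <- mean(x)
    s <- sd(x)
    tibble::tibble(variable = v, n = length(x), min = min(x),
                   max = max(x), mean = m, sd = s,
                   cv = if (m == 0) NA_real_ else s / m)
  })
}

#' Flag outlying rows
#'
#' Default rule: any variable beyond mean +/- `k` standard deviations
#' (k = 3). Alternative rule `"iqr"`: beyond the 1.5 IQR fences.
#' Flags are reported; nothing is removed.
#'
#' @param data Data frame.
#' @param variables Numeric column names to screen.
#' @param rule `"sd"` (default) or `"iqr"`.
#' @param k Multiplier for the SD rule (default 3) or the IQR rule
#'   (default 1.5 when `rule = "iqr"` and `k` is left at 3).
#' @return Logical vector, one flag per row; the flagged
#'   (row, variable) pairs are attached as attribute `"which"`.
#' @export
flag_outliers <- function(data, variables, rule = c("sd", "iqr"), k = 3) {
  rule <- match.arg(rule)
  check_columns(data, variables, "observations")
  if (rule == "iqr" && k == 3) k <- 1.5
  hits <- purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    lim <- if (rule == "sd") {
      mean(x, na.rm = TRUE) + c(-1, 1) * k * sd(x, na.rm = TRUE)
    } else {
      q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      c(q[1] - k * diff(q), q[2] + k * diff(q))
    }
    bad <- which(!is.na(x) & (x < lim[1] | x > lim[2]))
    tibble::tibble(row = bad, variable = v, value = x[bad])
  })
  flags <- seq_len(nrow(data)) %in% hits$row
  attr(flags, "which") <- hits
  flags
}

#' Shapiro-Wilk normality check per variable
#'
#' Reported, never used to drop data. Constant variables are masked.
#'
#' @param data Data frame.
#' @param variables Numeric column names.
#' @return Tibble `variable`, `statistic`, `p_value`.
#' @export
normality_check <- function(data, variables) {
  check_columns(data, variables, "observations")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) < 3 || sd(x) == 0) {
      return(tibble::tibble(variable = v, statistic = NA_real_,
                            p_value = NA_real_))
    }
    sw <- shapiro.test(x)
    tibble::tibble(variable = v, statistic = unname(sw$statistic),
                   p_value = sw$p.value)
  })
}

#' Collinearity diagnostics: tolerance and VIF
#'
#' For each predictor j, R^2_j from regressing it on the remaining
#' predictors; tolerance = 1 - R^2_j and VIF = 1/tolerance. Perfect
#' collinearity yields infinite VIF with a flag.
#'
#' @param data Data frame.
#' @param predictors Two or more numeric predictor column names.
#' @return Tibble `predictor`, `tolerance`, `vif`, `perfect` (logical).
#' @export
collinearity <- function(data, predictors) {
  check_columns(data, predictors, "observations")
  if (length(predictors) < 2) {
    stop_ricelwc("collinearity needs at least 2 predictors",
                 class = "ricelwc_error_validation")
  }
  d <- data[predictors]
  if (nrow(d) <= length(predictors)) {
    stop_ricelwc("need more observations than predictors",
                 class = "ricelwc_error_validation")
  }
  # VIF does not depend on the response; any non-degenerate one works
  d$.y <- seq_len(nrow(d))
  fit <- lm(.y ~ ., data = d)
  if (any(is.na(coef(fit)[-1]))) {
    return(tibble::tibble(predictor = predictors, tolerance = 0,
                          vif = Inf, perfect = TRUE))
  }
  v <- car::vif(fit)
  tibble::tibble(predictor = predictors, tolerance = 1 / unname(v),
                 vif = unname(v), perfect = FALSE)
}

#' Durbin-Watson statistic
#'
#' `sum(diff(e)^2) / sum(e^2)` over residuals in a fixed observation
#' order (the package sorts model rows by year, site and plot before
#' computing it; the ordering is the caller's responsibility here).
#' Approximately 2 under independence.
#'
#' @param residuals Ordered numeric residual vector (length >= 2).
#' @return The statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) {
    stop_ricelwc("need at least 2 residuals",
                 class = "ricelwc_error_validation")
  }
  den <- sum(residuals^2)
  if (den == 0) {
    stop_ricelwc("Durbin-Watson undefined for all-zero residuals",
                 class = "ricelwc_error_ratio")
  }
  sum(diff(residuals)^2) / den
}
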