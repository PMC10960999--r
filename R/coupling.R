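# Stage-wise ND-LWC lines, the quadratic slope/intercept analysis
# against stage-mean covariates, and the coupled two-predictor multiple
# linear regressions with year-split validation.

#' Year-based train/validation split rule
#'
#' @param train_year Year whose rows form the training set; all other
#'   years validate.
#' @return A split specification for [fit_coupled()] and
#'   [fit_stage_line()].
#' @export
year_split <- function(train_year = 2022) {
  structure(list(type = "year", train_year = train_year),
            class = "lwc_split")
}

#' Seeded random fraction split rule
#'
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return A split specification.
#' @export
fraction_split <- function(fraction = 0.7, seed = 1) {
  structure(list(type = "fraction", fraction = fraction, seed = seed),
            class = "lwc_split")
}

apply_split <- function(data, split) {
  if (is.null(split)) return(list(train = data, valid = NULL))
  stopifnot(inherits(split, "lwc_split"))
  if (split$type == "year") {
    check_columns(data, "year", "observations")
    if (length(unique(data$year)) < 2) {
      stop_ricelwc(
        "only one year present; a year split is impossible (use fraction_split())",
        class = "ricelwc_error_split")
    }
    train <- data[data$year == split$train_year, ]
    valid <- data[data$year != split$train_year, ]
  } else {
    parts <- split_data(data, fraction = split$fraction, seed = split$seed)
    train <- parts$train
    valid <- parts$test
  }
  if (nrow(train) == 0 || nrow(valid) == 0) {
    stop_ricelwc("empty train or validation partition",
                 class = "ricelwc_error_split")
  }
  list(train = train, valid = valid)
}

#' Stage-wise linear LWC ~ ND model
#'
#' Ordinary least squares of LWC on the normalized-difference index for
#' one growth stage, with optional held-out validation scored against
#' the 1:1 line (R^2 = 1 - SSres/SStot on the observed values, RMSE in
#' LWC units).
#'
#' @param data Training observations.
#' @param nd,lwc Column names of the index and the response.
#' @param validation Optional validation observations, or a split rule
#'   (see [year_split()], [fraction_split()]) applied to `data`.
#' @param stage Optional stage label carried into the result.
#' @return Object of class `lwc_stage_line` with slope `a`, intercept
#'   `b`, `r2_fit`, and `r2_pred`/`rmse` when validated.
#' @export
fit_stage_line <- function(data, nd = "ND", lwc = "LWC",
                           validation = NULL, stage = NA_character_) {
  if (inherits(validation, "lwc_split")) {
    parts <- apply_split(data, validation)
    data <- parts$train
    validation <- parts$valid
  }
  check_columns(data, c(nd, lwc), "training data")
  if (nrow(data) < 3) {
    stop_ricelwc("need at least 3 training samples",
                 class = "ricelwc_error_validation")
  }
  if (sd(data[[nd]]) == 0) {
    stop_ricelwc("constant ND: rank-deficient fit",
                 class = "ricelwc_error_rank")
  }
  fit <- lm(stats::reformulate(nd, lwc), data = data)
  res <- list(
    stage = stage, a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
    r2_fit = summary(fit)$r.squared,
    n_train = nrow(data), fit = fit,
    nd = nd, lwc = lwc,
    r2_pred = NA_real_, rmse = NA_real_, n_valid = 0L, validation = NULL
  )
  if (!is.null(validation)) {
    pred <- predict(fit, newdata = validation)
    m <- regression_metrics(validation[[lwc]], pred)
    res$r2_pred <- m$r2
    res$rmse <- m$rmse
    res$n_valid <- nrow(validation)
    res$validation <- tibble::tibble(observed = validation[[lwc]],
                                     predicted = pred)
  }
  structure(res, class = "lwc_stage_line")
}

#' @export
print.lwc_stage_line <- function(x, ...) {
  cat(sprintf("LWC = %.4f * %s + %.4f  [%s; R2_fit = %.3f",
              x$a, x$nd, x$b,
              ifelse(is.na(x$stage), "stage n/a", x$stage), x$r2_fit))
  if (x$n_valid > 0) {
    cat(sprintf(", R2_pred = %.3f, RMSE = %.4f (n = %d/%d)",
                x$r2_pred, x$rmse, x$n_train, x$n_valid))
  }
  cat("]\n")
  invisible(x)
}

#' @export
tidy.lwc_stage_line <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$nd),
                 estimate = c(x$b, x$a))
}

#' @export
glance.lwc_stage_line <- function(x, ...) {
  tibble::tibble(stage = x$stage, a = x$a, b = x$b, r2_fit = x$r2_fit,
                 r2_pred = x$r2_pred, rmse = x$rmse,
                 n_train = x$n_train, n_valid = x$n_valid)
}

#' Quadratic relations of stage-line slope and intercept with covariates
#'
#' Least-squares quadratic of each of the stage-line slope `a` and
#' intercept `b` on each stage-mean covariate. With four stages the fit
#' has one residual degree of freedom and with three it is saturated
#' (R^2 = 1); the relations are therefore reported descriptively,
#' without significance claims.
#'
#' @param stage_lines Tibble with columns `stage`, `a`, `b` (e.g. from
#'   `glance()` on [fit_stage_line()] results).
#' @param stage_covariates Tibble with `stage` and one column per
#'   stage-mean covariate (e.g. SPAD, FvFm, CWSI).
#' @return Tibble of class `lwc_quadratics`: `target`, `covariate`,
#'   `c0`, `c1`, `c2` (coefficients of c0 + c1*x + c2*x^2) and `r2`.
#' @export
slope_intercept_analysis <- function(stage_lines, stage_covariates) {
  check_columns(stage_lines, c("stage", "a", "b"), "stage_lines")
  check_columns(stage_covariates, "stage", "stage_covariates")
  d <- dplyr::inner_join(stage_lines, stage_covariates, by = "stage")
  if (nrow(d) < 3) {
    stop_ricelwc("need at least 3 stages for the quadratic analysis",
                 class = "ricelwc_error_validation")
  }
  covs <- setdiff(names(stage_covariates), "stage")
  out <- tidyr::expand_grid(target = c("slope_a", "intercept_b"),
                            covariate = covs) %>%
    purrr::pmap(function(target, covariate) {
      y <- if (target == "slope_a") d$a else d$b
      x <- d[[covariate]]
      fit <- lm(y ~ x + I(x^2))
      cf <- coef(fit)
      ss_res <- sum(resid(fit)^2)
      ss_tot <- sum((y - mean(y))^2)
      tibble::tibble(target = target, covariate = covariate,
                     c0 = unname(cf[1]), c1 = unname(cf[2]),
                     c2 = unname(cf[3]),
                     r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
    }) %>%
    dplyr::bind_rows()
  class(out) <- c("lwc_quadratics", class(out))
  out
}

#' Coupled two-predictor linear model of LWC
#'
#' Multiple linear regression `LWC = b0 + b1 * ND + b2 * covariate`
#' fitted on the training partition and scored on the validation
#' partition (R^2 as 1 - SSres/SStot against the observed values, RMSE
#' in LWC units). Collinearity (tolerance/VIF) and the Durbin-Watson
#' statistic of the training residuals (rows ordered by year, site,
#' plot_id where present) are attached.
#'
#' @param data Observations with the index, covariate, response and any
#'   split columns.
#' @param nd,covariate,lwc Column names.
#' @param split A split rule from [year_split()] (default: train on
#'   2022) or [fraction_split()], or `NULL` to fit on everything with no
#'   validation.
#' @param stage Optional stage label.
#' @return Object of class `lwc_coupled`.
#' @export
fit_coupled <- function(data, nd = "ND", covariate = "CWSI",
                        lwc = "LWC", split = year_split(2022),
                        stage = NA_character_) {
  check_columns(data, c(nd, covariate, lwc), "observations")
  ord <- intersect(c("year", "site", "plot_id"), names(data))
  if (length(ord) > 0) {
    data <- dplyr::arrange(data, dplyr::across(dplyr::all_of(ord)))
  }
  parts <- apply_split(data, split)
  train <- parts$train
  valid <- parts$valid
  fit <- lm(stats::reformulate(c(nd, covariate), lwc), data = train)
  res <- list(
    stage = stage, predictors = c(nd, covariate), lwc = lwc,
    coefficients = coef(fit),
    model_r2 = summary(fit)$r.squared,
    n_train = nrow(train), fit = fit,
    collinearity = collinearity(train, c(nd, covariate)),
    dw = durbin_watson(resid(fit)),
    prediction_r2 = NA_real_, rmse = NA_real_, n_valid = 0L,
    validation = NULL
  )
  if (!is.null(valid)) {
    pred <- predict(fit, newdata = valid)
    m <- regression_metrics(valid[[lwc]], pred)
    res$prediction_r2 <- m$r2
    res$rmse <- m$rmse
    res$n_valid <- nrow(valid)
    res$validation <- tibble::tibble(observed = valid[[lwc]],
                                     predicted = pred)
  }
  structure(res, class = "lwc_coupled")
}

#' @export
print.lwc_coupled <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("LWC = %.3f%s + %.3f*%s + %.3f*%s  [%s]\n",
              cf[1], "", cf[2], x$predictors[1], cf[3], x$predictors[2],
              ifelse(is.na(x$stage), "stage n/a", x$stage)))
  cat(sprintf("  model R2 = %.3f (n = %d)", x$model_r2, x$n_train))
  if (x$n_valid > 0) {
    cat(sprintf("; prediction R2 = %.3f, RMSE = %.4f (n = %d)",
                x$prediction_r2, x$rmse, x$n_valid))
  }
  cat(sprintf("; DW = %.2f\n", x$dw))
  invisible(x)
}

#' @export
tidy.lwc_coupled <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
  if (conf.int) {
    ci <- confint(x$fit, level = conf.level)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  }
  out
}

#' @export
glance.lwc_coupled <- function(x, ...) {
  tibble::tibble(
    stage = x$stage, covariate = x$predictors[2],
    model_r2 = x$model_r2, prediction_r2 = x$prediction_r2,
    rmse = x$rmse, n_train = x$n_train, n_valid = x$n_valid,
    dw = x$dw, max_vif = max(x$collinearity$vif)
  )
}

#' Improvement of coupled models over the ND-only line
#'
#' Per coupled model, the absolute and relative change in model and
#' prediction R^2 relative to the single-index stage line. Both fits
#' must use the same train/validation samples.
#'
#' @param stage_line An `lwc_stage_line` fitted on the same partition.
#' @param coupled A single `lwc_coupled` or a list of them.
#' @return Tibble with one row per coupled model.
#' @export
compare_models <- function(stage_line, coupled) {
  stopifnot(inherits(stage_line, "lwc_stage_line"))
  if (inherits(coupled, "lwc_coupled")) coupled <- list(coupled)
  purrr::map_dfr(coupled, function(cm) {
    if (cm$n_train != stage_line$n_train ||
        cm$n_valid != stage_line$n_valid) {
      stop_ricelwc("compared models use different sample partitions",
                   class = "ricelwc_error_validation")
    }
    tibble::tibble(
      stage = cm$stage, covariate = cm$predictors[2],
      r2_model_nd = stage_line$r2_fit, r2_model_coupled = cm$model_r2,
      delta_model = cm$model_r2 - stage_line$r2_fit,
      rel_model = cm$model_r2 / stage_line$r2_fit - 1,
      r2_pred_nd = stage_line$r2_pred,
      r2_pred_coupled = cm$prediction_r2,
      delta_pred = cm$prediction_r2 - stage_line$r2_pred,
      rel_pred = cm$prediction_r2 / stage_line$r2_pred - 1
    )
  })
}

#' 1:1 validation scatter of a fitted model
#'
#' Predicted against observed LWC with the identity line.
#'
#' @param object An `lwc_stage_line` or `lwc_coupled` with validation
#'   data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_validation <- function(object, ...) {
  if (is.null(object$validation)) {
    stop_ricelwc("model carries no validation data",
                 class = "ricelwc_error_validation")
  }
  lab <- if (inherits(object, "lwc_coupled")) {
    sprintf("R2 = %.2f, RMSE = %.3f", object$prediction_r2, object$rmse)
  } else {
    sprintf("R2 = %.2f, RMSE = %.3f", object$r2_pred, object$rmse)
  }
  ggplot2::ggplot(object$validation,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "Observed LWC", y = "Predicted LWC") +
    ggplot2::theme_minimal()
}
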