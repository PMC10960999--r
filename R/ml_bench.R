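# Machine-learning benchmark on the coupled feature set: decision tree,
# random forest, k-nearest neighbours and gradient-boosted trees against
# multiple linear regression, with a seeded 70/30 split and R^2/RMSE on
# both partitions.

#' Coefficient of determination and root mean square error
#'
#' `r2 = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)` and
#' `rmse = sqrt(mean((x - xhat)^2))`. R^2 is the fraction of variance
#' explained; it can be negative for predictions worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return List with `r2` and `rmse`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop_ricelwc("observed and predicted must have equal non-zero length",
                 class = "ricelwc_error_validation")
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_ricelwc("R^2 undefined: observed values have zero variance",
                 class = "ricelwc_error_ratio")
  }
  list(r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / length(observed)))
}

#' Seeded random train/test partition
#'
#' Sizes are `ceiling(fraction * n)` for training and the remainder for
#' testing; partitions are disjoint and exhaustive.
#'
#' @param data Data frame with at least 10 rows.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train`, `test` and the integer `train_idx`.
#' @export
split_data <- function(data, fraction = 0.7, seed = 1) {
  n <- nrow(data)
  if (n < 10) {
    stop_ricelwc("need at least 10 rows to split",
                 class = "ricelwc_error_validation")
  }
  if (fraction <= 0 || fraction >= 1) {
    stop_ricelwc("fraction must be in (0, 1)",
                 class = "ricelwc_error_validation")
  }
  set.seed(seed)
  idx <- sort(sample.int(n, ceiling(fraction * n)))
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE],
       train_idx = idx)
}

default_hyperparameters <- function() {
  list(
    DT = list(maxdepth = 10),
    RF = list(num_trees = 100, min_node_size = 5),
    KNN = list(k = 3),
    GBDT = list(num_trees = 100, max_depth = 3, eta = 0.1),
    MLR = list()
  )
}

#' Fit one regression algorithm and score both partitions
#'
#' Algorithms: `DT` (rpart, depth-limited, grown without the default
#' complexity pruning so depth is the binding constraint), `RF`
#' (ranger), `KNN` (caret k-nearest neighbours on features standardized
#' with training-set statistics), `GBDT` (xgboost, squared-error
#' objective, single thread) and `MLR` (ordinary least squares). R^2
#' and RMSE come from [regression_metrics()] on each partition.
#'
#' @param algorithm One of `"DT"`, `"RF"`, `"KNN"`, `"GBDT"`, `"MLR"`.
#' @param train,test Disjoint data frames holding `features` and
#'   `response`.
#' @param features Character vector of predictor column names.
#' @param response Response column name (default `"LWC"`).
#' @param hyperparameters Named list overriding the defaults for this
#'   algorithm (see `Details`).
#' @param seed Integer seed for the stochastic learners.
#' @return One-row tibble: `algorithm`, `r2_sim`, `rmse_sim`, `r2_val`,
#'   `rmse_val`, `seed`, `n_train`, `n_test` and a list-column
#'   `hyperparameters`; test-set predictions attached as attribute
#'   `"predictions"`.
#' @export
fit_predict <- function(algorithm, train, test, features,
                        response = "LWC", hyperparameters = list(),
                        seed = 1) {
  known <- names(default_hyperparameters())
  if (!algorithm %in% known) {
    stop_ricelwc(sprintf("unknown algorithm '%s' (expected one of %s)",
                         algorithm, paste(known, collapse = ", ")),
                 class = "ricelwc_error_validation")
  }
  check_columns(train, c(features, response), "training data")
  check_columns(test, c(features, response), "test data")
  if (sd(train[[response]]) == 0) {
    stop_ricelwc("constant training response",
                 class = "ricelwc_error_validation")
  }
  hp <- modifyList(default_hyperparameters()[[algorithm]], hyperparameters)
  if (algorithm %in% c("RF", "GBDT") &&
      (is.null(hp$num_trees) || hp$num_trees < 1)) {
    stop_ricelwc(sprintf("%s needs num_trees >= 1", algorithm),
                 class = "ricelwc_error_validation")
  }
  form <- stats::reformulate(features, response)
  xtr <- as.matrix(train[features])
  xte <- as.matrix(test[features])
  ytr <- train[[response]]
  set.seed(seed)

  predictor <- switch(
    algorithm,
    MLR = {
      fit <- lm(form, data = train)
      function(newdata, x) predict(fit, newdata = newdata)
    },
    DT = {
      fit <- rpart::rpart(
        form, data = train, method = "anova",
        control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                       minsplit = 2, minbucket = 1,
                                       cp = 0, xval = 0))
      function(newdata, x) predict(fit, newdata = newdata)
    },
    RF = {
      fit <- ranger::ranger(
        form, data = train, num.trees = hp$num_trees,
        mtry = length(features),
        min.node.size = hp$min_node_size, seed = seed, num.threads = 1)
      function(newdata, x) predict(fit, data = newdata)$predictions
    },
    KNN = {
      ctr <- colMeans(xtr)
      scl <- apply(xtr, 2, sd)
      scl[scl == 0] <- 1
      ztr <- scale(xtr, center = ctr, scale = scl)
      fit <- caret::knnreg(ztr, ytr, k = hp$k)
      function(newdata, x) {
        predict(fit, newdata = scale(x, center = ctr, scale = scl))
      }
    },
    GBDT = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
      fit <- xgboost::xgb.train(
        params = list(max_depth = hp$max_depth, eta = hp$eta,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = dtr, nrounds = hp$num_trees, verbose = 0)
      function(newdata, x) predict(fit, xgboost::xgb.DMatrix(x))
    }
  )

  pred_tr <- predictor(train, xtr)
  pred_te <- predictor(test, xte)
  m_tr <- regression_metrics(train[[response]], pred_tr)
  m_te <- regression_metrics(test[[response]], pred_te)
  out <- tibble::tibble(
    algorithm = algorithm,
    r2_sim = m_tr$r2, rmse_sim = m_tr$rmse,
    r2_val = m_te$r2, rmse_val = m_te$rmse,
    seed = seed, n_train = nrow(train), n_test = nrow(test),
    hyperparameters = list(hp)
  )
  attr(out, "predictions") <- tibble::tibble(
    observed = test[[response]], predicted = pred_te)
  out
}

#' Benchmark all algorithms on one feature set
#'
#' Applies a seeded 70/30 split and runs each algorithm through
#' [fit_predict()] with identical partitions.
#'
#' @param data Observations (features + response).
#' @param features Predictor column names, e.g. `c("ND", "CWSI")`.
#' @param response Response column name.
#' @param algorithms Algorithms to run.
#' @param fraction Training fraction.
#' @param seed Integer seed (split and stochastic learners).
#' @param hyperparameters Named list of per-algorithm overrides, e.g.
#'   `list(KNN = list(k = 5))`.
#' @return Tibble of class `lwc_benchmark`, one row per algorithm.
#' @export
benchmark_algorithms <- function(data, features = c("ND", "CWSI"),
                                 response = "LWC",
                                 algorithms = c("DT", "RF", "KNN",
                                                "GBDT", "MLR"),
                                 fraction = 0.7, seed = 1,
                                 hyperparameters = list()) {
  parts <- split_data(data, fraction = fraction, seed = seed)
  out <- purrr::map_dfr(algorithms, function(alg) {
    fit_predict(alg, parts$train, parts$test, features,
                response = response,
                hyperparameters = hyperparameters[[alg]] %||% list(),
                seed = seed)
  })
  class(out) <- c("lwc_benchmark", class(out))
  attr(out, "split") <- list(fraction = fraction, seed = seed,
                             train_idx = parts$train_idx)
  out
}

#' Ratio table of each algorithm against MLR
#'
#' R^2 and RMSE ratios (algorithm / MLR) on both partitions, the style
#' of a fold-change comparison.
#'
#' @param results An `lwc_benchmark` (must contain an MLR row).
#' @return Tibble with one row per non-MLR algorithm.
#' @export
compare_to_mlr <- function(results) {
  if (!"MLR" %in% results$algorithm) {
    stop_ricelwc("results contain no MLR row",
                 class = "ricelwc_error_validation")
  }
  mlr <- results[results$algorithm == "MLR", ]
  safe_ratio <- function(x, base) {
    if (base == 0) NA_real_ else x / base
  }
  results %>%
    dplyr::filter(.data$algorithm != "MLR") %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      r2_sim_ratio = safe_ratio(.data$r2_sim, mlr$r2_sim),
      r2_val_ratio = safe_ratio(.data$r2_val, mlr$r2_val),
      rmse_sim_ratio = safe_ratio(.data$rmse_sim, mlr$rmse_sim),
      rmse_val_ratio = safe_ratio(.data$rmse_val, mlr$rmse_val)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("algorithm", dplyr::ends_with("_ratio"))
}
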