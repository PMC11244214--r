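#' Distribution-preserving train/test split
#'
#' Splits the feature table into `train_fraction` / remainder so that the
#' training part spans the full observed target range: rows are stratified
#' over 10 target-quantile bins, and the global minimum and maximum target
#' rows are forced into the training part. Train size is
#' `floor(train_fraction * n)`.
#'
#' @param table a `lur_features` table with a `target` column.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed for the within-bin shuffling.
#' @param bins number of target-quantile strata.
#' @return list with `train` and `test` data frames.
#' @export
split_table <- function(table, train_fraction = 0.7, seed = 1, bins = 10) {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n)
  y <- table$target
  with_seed(seed, {
    if (n < 2 * bins) {
      warning("too few rows for stratification; plain random split")
      idx <- sample.int(n, n_train)
    } else {
      brks <- unique(lur_quantile(y, seq(0, 1, length.out = bins + 1)))
      b <- findInterval(y, brks, rightmost.closed = TRUE, all.inside = TRUE)
      forced <- unique(c(which.min(y), which.max(y)))
      pool <- setdiff(sample.int(n), forced)      # shuffled once
      pool <- pool[order(b[pool])]                # group by stratum, keep shuffle
      # take proportionally from each stratum by interleaving strata order
      take <- n_train - length(forced)
      by_bin <- split(pool, b[pool])
      picked <- integer(0)
      while (length(picked) < take) {
        for (bb in seq_along(by_bin)) {
          if (length(picked) >= take) break
          if (length(by_bin[[bb]]) > 0) {
            picked <- c(picked, by_bin[[bb]][1])
            by_bin[[bb]] <- by_bin[[bb]][-1]
          }
        }
      }
      idx <- c(forced, picked)
    }
    list(train = table[idx, , drop = FALSE],
         test = table[-idx, , drop = FALSE])
  })
}

#' Fit a Monte-Carlo random-forest ensemble
#'
#' The core estimator: one random-forest regressor (squared-error splits,
#' bootstrap aggregation, 100 trees) per seed. The default split search
#' considers p/3 features per node - the classic regression-forest rule,
#' which approximates an exhaustive search while staying affordable; see
#' `mtry`. Seeds default to `0:49`; the full campaign-scale setting is
#' `0:999`. Each seed gives a deterministic model.
#'
#' @param train training `lur_features` table (with `target`).
#' @param seeds integer vector of Monte-Carlo seeds.
#' @param num_trees trees per forest.
#' @param mtry features tried per split: `"third"` (default) the classic
#'   p/3 regression rule, `"sqrt"` the backend's `floor(sqrt(p))`, `"all"`
#'   an exhaustive split search, or an integer.
#' @param model_id label carried into reports (e.g. `"baseline"`).
#' @return an object of class `lur_ensemble` with elements `models`,
#'   `seeds`, `features`, `model_id`, `num_trees`.
#' @export
lur_ensemble <- function(train, seeds = 0:49, num_trees = 100,
                         mtry = "third", model_id = "baseline") {
  if (nrow(train) == 0) stop("empty training table")
  if (!"target" %in% names(train)) stop("training table must carry a target")
  feats <- feature_names(train)
  ok <- vapply(train[feats], is.numeric, TRUE)
  if (!all(ok))
    stop("non-numeric feature column(s): ", paste(feats[!ok], collapse = ", "))
  x <- as.matrix(train[feats])
  y <- train$target
  mtry_n <- resolve_mtry(mtry, length(feats))
  # the backend treats seed 0 as "unseeded"; shift by one so that the
  # campaign convention of seeds 0..k stays deterministic
  models <- lapply(seeds, function(s)
    ranger::ranger(x = x, y = y, num.trees = num_trees, mtry = mtry_n,
                   importance = "impurity", seed = as.integer(s) + 1L,
                   num.threads = 1))
  structure(list(models = models, seeds = as.integer(seeds),
                 features = feats, model_id = model_id,
                 num_trees = num_trees, n_train = nrow(train)),
            class = "lur_ensemble")
}

resolve_mtry <- function(mtry, p) {
  if (is.null(mtry) || identical(mtry, "sqrt")) return(max(1L, floor(sqrt(p))))
  if (identical(mtry, "all")) return(p)
  if (identical(mtry, "third")) return(max(1L, floor(p / 3)))
  min(as.integer(mtry), p)
}

#' @export
print.lur_ensemble <- function(x, ...) {
  cat(sprintf("<lur_ensemble> '%s': %d forests (%d trees each), %d features, %d training rows\n",
              x$model_id, length(x$models), x$num_trees,
              length(x$features), x$n_train))
  invisible(x)
}

#' Predict from an ensemble
#'
#' @param object a `lur_ensemble`.
#' @param newdata data frame or matrix containing the ensemble's feature
#'   columns.
#' @param per_seed return the n x n_seeds matrix of per-seed predictions
#'   instead of the ensemble mean.
#' @param ... unused.
#' @return numeric vector (ensemble-mean prediction) or matrix.
#' @export
predict.lur_ensemble <- function(object, newdata, per_seed = FALSE, ...) {
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss) > 0)
    stop("newdata lacks feature column(s): ", paste(head(miss, 5), collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[object$features])
  p <- vapply(object$models, function(m)
    predict(m, x, num.threads = 1)$predictions, numeric(nrow(x)))
  if (nrow(x) == 1) p <- matrix(p, nrow = 1)
  if (per_seed) p else rowMeans(p)
}

#' @export
summary.lur_ensemble <- function(object, ...) {
  imp <- Reduce(`+`, lapply(object$models, ranger::importance)) /
    length(object$models)
  top <- sort(imp, decreasing = TRUE)
  cat(sprintf("Monte-Carlo random-forest ensemble '%s'\n", object$model_id))
  cat(sprintf("  %d seeds, %d trees, %d features, %d training rows\n",
              length(object$seeds), object$num_trees,
              length(object$features), object$n_train))
  cat("  top impurity importances (seed-mean):\n")
  print(round(head(top, 8), 3))
  invisible(list(importance = imp))
}

#' Regression metrics
#'
#' Standard validation metrics: MAE, MSE, RMSE, NRMSE (RMSE divided by the
#' observed range, also called scatter index) and R2 = 1 - SS_res/SS_tot
#' (not clipped; may be negative out of sample).
#'
#' @param predictions,observations equal-length numeric vectors (n >= 2);
#'   observations must not be constant (NRMSE undefined).
#' @return a named list of class `metric_set`: `mae`, `mse`, `rmse`,
#'   `nrmse`, `r2`.
#' @export
evaluate <- function(predictions, observations) {
  if (length(predictions) != length(observations) || length(observations) < 2)
    stop("need equal-length vectors of length >= 2")
  rng <- diff(range(observations))
  if (rng == 0) stop("observations are constant; NRMSE undefined")
  err <- predictions - observations
  mse <- mean(err^2)
  structure(list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
                 nrmse = sqrt(mse) / rng,
                 r2 = 1 - sum(err^2) / sum((observations - mean(observations))^2)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("MAE %.3f  MSE %.3f  RMSE %.3f  NRMSE %.3f  R2 %.3f\n",
              x$mae, x$mse, x$rmse, x$nrmse, x$r2))
  invisible(x)
}
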