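#' Hold-out validation of an ensemble
#'
#' Predicts the withheld test split with every seed of the ensemble and
#' summarises performance: the aggregate [evaluate()] metrics of the
#' ensemble-mean prediction, per-seed metrics, and Q-Q pairs (sorted
#' observed vs sorted mean-predicted).
#'
#' @param ensemble a [lur_ensemble].
#' @param test test `lur_features` table (disjoint from training).
#' @return a `lur_validation` object.
#' @export
hov_validate <- function(ensemble, test) {
  p <- predict(ensemble, test, per_seed = TRUE)
  obs <- test$target
  mean_pred <- rowMeans(p)
  per_seed <- t(apply(p, 2, function(pk) unlist(evaluate(pk, obs))))
  structure(list(model_id = ensemble$model_id, mode = "hov",
                 metrics = evaluate(mean_pred, obs),
                 per_seed_metrics = as.data.frame(per_seed),
                 qq = data.frame(observed = sort(obs),
                                 predicted = sort(mean_pred)),
                 observed = obs, predicted = mean_pred),
            class = "lur_validation")
}

#' @export
print.lur_validation <- function(x, ...) {
  cat(sprintf("<lur_validation> %s (%s): ", x$model_id, x$mode))
  print(x$metrics)
  invisible(x)
}

#' Observed local maximum at a reference station
#'
#' Applies the same background convention as the mobile preprocessing: the
#' `q` quantile of the station's series is subtracted as background, and
#' the median of the background-subtracted concentrations over the
#' measurement days is returned. With daily records the daily maximum is
#' the day's value; an even number of days gives the mean of the central
#' pair.
#'
#' @param record a `station_record`.
#' @param measurement_dates days on which mobile measurements took place.
#' @param q background quantile.
#' @return observed local concentration, ug/m3.
#' @export
station_observed_local_max <- function(record, measurement_dates, q = 0.05) {
  hit <- record$dates %in% measurement_dates
  if (!any(hit))
    stop("station ", record$station_id,
         " has no data on the measurement dates")
  bg <- lur_quantile(record$pm25, q)
  local <- record$pm25 - bg
  stats::median(local[hit])
}

#' Station-style validation of model variants
#'
#' Predicts the station feature rows with every seed of every model variant
#' and compares against the stations' observed local maxima. Reports, per
#' variant: per-station RMSE over seeds, per-station absolute-error
#' distributions, and the pooled metrics of the ensemble-mean predictions.
#' Station targets are never used in training; this is strictly external
#' validation.
#'
#' @param ensembles named list of [lur_ensemble]s (one per model variant).
#' @param station_features `lur_features` table for the stations (no
#'   target needed); its `kept_rows` attribute aligns rows with `records`.
#' @param records list of `station_record`s.
#' @param measurement_dates days with mobile measurements.
#' @param q background quantile for the observed series.
#' @return named list of `lur_validation` objects, one per variant, each
#'   with `per_station` (data frame) and `abs_errors` (station x seed).
#' @export
station_validate <- function(ensembles, station_features, records,
                             measurement_dates, q = 0.05) {
  kept <- attr(station_features, "kept_rows") %||% seq_len(nrow(station_features))
  skipped <- setdiff(seq_along(records), kept)
  if (length(skipped) > 0)
    message("station(s) without complete features skipped: ",
            paste(vapply(records[skipped], `[[`, "", "station_id"),
                  collapse = ", "))
  recs <- records[kept]
  obs <- vapply(recs, station_observed_local_max, 0,
                measurement_dates = measurement_dates, q = q)
  ids <- vapply(recs, `[[`, "", "station_id")
  lapply(ensembles, function(ens) {
    p <- predict(ens, station_features, per_seed = TRUE)  # station x seed
    err <- sweep(p, 1, obs)
    per_station <- data.frame(
      station_id = ids,
      classification = vapply(recs, `[[`, "", "classification"),
      observed = obs,
      predicted = rowMeans(p),
      rmse = sqrt(rowMeans(err^2)))
    mean_pred <- rowMeans(p)
    pooled <- if (length(obs) >= 2 && diff(range(obs)) > 0)
      evaluate(mean_pred, obs) else NULL
    structure(list(model_id = ens$model_id, mode = "stations",
                   metrics = pooled,
                   per_station = per_station,
                   abs_errors = abs(err),
                   qq = data.frame(observed = sort(obs),
                                   predicted = sort(mean_pred)),
                   observed = obs, predicted = mean_pred),
              class = "lur_validation")
  })
}

#' Signed residual summary per station
#'
#' @param report a station-mode `lur_validation`.
#' @return data frame with per-station mean signed error (predicted minus
#'   observed), MAE, and an over/under-estimation flag.
#' @export
residual_summary <- function(report) {
  ps <- report$per_station
  if (is.null(ps)) stop("report has no per-station results")
  resid <- ps$predicted - ps$observed
  data.frame(station_id = ps$station_id,
             mean_error = resid,
             mae = rowMeans(report$abs_errors),
             direction = ifelse(resid > 0, "over", "under"))
}

#' Q-Q plot of a validation report
#'
#' Sorted observed vs sorted predicted concentrations with the 1:1 line.
#'
#' @param x a `lur_validation`.
#' @param ... passed to [plot()].
#' @export
plot.lur_validation <- function(x, ...) {
  graphics::plot(x$qq$observed, x$qq$predicted,
                 xlab = "observed PM2.5 (ug/m3)",
                 ylab = "predicted PM2.5 (ug/m3)",
                 main = sprintf("%s (%s)", x$model_id, x$mode), ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
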