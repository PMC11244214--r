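#' kappa-Koehler humidity correction factor
#'
#' Optical particle counters over-read mass at high relative humidity because
#' hygroscopic particles swell with water. The mass-growth correction factor
#' is
#' \deqn{C = 1 + \frac{\kappa/\rho}{1/RH - 1}}
#' with hygroscopicity \eqn{\kappa}, particle density \eqn{\rho} (g/cm3) and
#' relative humidity as a fraction in (0, 1). `C >= 1` and is non-decreasing
#' in RH; the corrected (dry) reading is raw / C.
#'
#' @param rh relative humidity as a fraction, strictly in (0, 1).
#' @param kappa hygroscopicity kappa (>= 0); 0.4 is typical for aged urban
#'   aerosol.
#' @param rho particle density in g/cm3 (> 0); default 1.6.
#' @return correction factor(s) `C`, dimensionless.
#' @examples
#' correction_factor(0.8, kappa = 0.4, rho = 1.6)  # 2
#' @export
correction_factor <- function(rh, kappa = 0.4, rho = 1.6) {
  if (any(rh <= 0 | rh >= 1)) stop("rh must be strictly inside (0, 1)")
  if (kappa < 0) stop("kappa must be >= 0")
  if (rho <= 0) stop("rho must be > 0")
  1 + (kappa / rho) / (1 / rh - 1)
}

#' Correct raw PM readings for hygroscopic growth
#'
#' Divides each raw reading by the correction factor at the sample's
#' relative humidity. Samples with missing RH are dropped and counted in the
#' `n_dropped_rh` attribute.
#'
#' @param track a `lur_track` data frame with `pm25_raw` and `rh_pct`.
#' @param kappa,rho see [correction_factor()].
#' @return the track with an added `pm25_corrected` column.
#' @export
correct_pm <- function(track, kappa = 0.4, rho = 1.6) {
  miss <- is.na(track$rh_pct)
  n_dropped <- sum(miss)
  out <- track[!miss, , drop = FALSE]
  C <- correction_factor(out$rh_pct / 100, kappa = kappa, rho = rho)
  out$pm25_corrected <- out$pm25_raw / C
  attr(out, "n_dropped_rh") <- n_dropped
  out
}

#' Remove extreme values by percentile trimming
#'
#' Drops values strictly below the `trim_fraction` quantile and strictly
#' above the `1 - trim_fraction` quantile (linear-interpolation quantiles).
#'
#' @param values numeric series, length >= 20.
#' @param trim_fraction fraction in `[0, 0.5)`; default 0.05 removes the top
#'   and bottom 5th percentile.
#' @return logical-indexed subset of `values` that survives trimming.
#' @export
trim_outliers <- function(values, trim_fraction = 0.05) {
  if (length(values) < 20) stop("series too short to trim (need >= 20)")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  if (trim_fraction == 0) return(values)
  q <- lur_quantile(values, c(trim_fraction, 1 - trim_fraction))
  values[values >= q[1] & values <= q[2]]
}

#' Temporal median over tumbling windows
#'
#' Reduces a track to one sample per non-overlapping window of
#' `window` seconds: the median concentration, the window-center timestamp
#' and the mean position. A short final window is kept as long as it holds
#' at least one sample.
#'
#' @param track a track data frame with `time`, `x`, `y` and the value
#'   column named by `value_col`.
#' @param window window length in seconds (> 0); default 30.
#' @param value_col which column to take medians of.
#' @return data frame with `time`, `x`, `y` and the reduced value column.
#' @export
temporal_median <- function(track, window = 30, value_col = "pm25_corrected") {
  if (window <= 0) stop("window must be > 0")
  if (is.unsorted(track$time, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  t0 <- track$time[1]
  bin <- floor((track$time - t0) / window)
  split_idx <- split(seq_len(nrow(track)), bin)
  rows <- lapply(split_idx, function(ix) {
    data.frame(time = t0 + (bin[ix[1]] + 0.5) * window,
               x = mean(track$x[ix]), y = mean(track$y[ix]),
               value = stats::median(track[[value_col]][ix]))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- value_col
  rownames(out) <- NULL
  out
}

#' Subtract the background concentration
#'
#' The background is the `q` quantile of the series (default the 5th
#' percentile); it is subtracted from every value so only the local signal
#' remains. Negative values are retained, not clipped - clipping would bias
#' round means. Applied per round, this also removes a linear sensor drift
#' between rounds.
#'
#' @param values numeric series, non-empty.
#' @param q background quantile in `[0, 1)`.
#' @return list with `local` (the shifted series) and `background`.
#' @export
subtract_background <- function(values, q = 0.05) {
  if (length(values) == 0) stop("empty series")
  bg <- lur_quantile(values, q)
  list(local = values - bg, background = bg)
}

#' Preprocess one measurement round
#'
#' Fixed pipeline order: humidity-correct, trim percentile outliers, tumbling
#' temporal median, subtract the per-round background. Each round is handled
#' independently of all others.
#'
#' @param track raw `lur_track` for one round.
#' @param kappa,rho humidity-correction parameters.
#' @param trim_fraction,median_window,background_quantile stage parameters.
#' @return data frame with `time`, `x`, `y`, `pm25_corrected`, `pm25_local`,
#'   `round`, `area`; attributes `background` and `report` (counts per
#'   stage).
#' @export
preprocess_track <- function(track, kappa = 0.4, rho = 1.6,
                             trim_fraction = 0.05, median_window = 30,
                             background_quantile = 0.05) {
  n0 <- nrow(track)
  corr <- correct_pm(track, kappa = kappa, rho = rho)
  kept <- trim_outliers(corr$pm25_corrected, trim_fraction)
  keep_idx <- corr$pm25_corrected >= min(kept) & corr$pm25_corrected <= max(kept)
  if (trim_fraction == 0) keep_idx <- rep(TRUE, nrow(corr))
  trimmed <- corr[keep_idx, , drop = FALSE]
  med <- temporal_median(trimmed, window = median_window)
  bg <- subtract_background(med$pm25_corrected, background_quantile)
  med$pm25_local <- bg$local
  med$round <- track$round[1]
  med$area <- track$area[1]
  attr(med, "background") <- bg$background
  attr(med, "report") <- c(n_raw = n0,
                           n_dropped_rh = attr(corr, "n_dropped_rh"),
                           n_trimmed = nrow(corr) - nrow(trimmed),
                           n_windows = nrow(med))
  med
}
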