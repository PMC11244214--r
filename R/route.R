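#' Build the idealised route for one area
#'
#' Resamples each round's track to a common arc-length parameterisation,
#' averages positions pointwise across rounds, and resamples the mean path
#' to uniform spacing. With a single track the result is simply that track
#' resampled.
#'
#' @param tracks list of track data frames for one area (columns `x`, `y`).
#' @param spacing target spacing of route points in meters; default 25 so
#'   adjacent 25 m buffers abut.
#' @param max_length_mismatch maximal relative arc-length disagreement
#'   between rounds before the offending round is rejected.
#' @return matrix of route points (`x`, `y`), ordered along the route.
#' @export
build_ideal_route <- function(tracks, spacing = 25,
                              max_length_mismatch = 0.2) {
  if (length(tracks) < 1) stop("need at least one track")
  areas <- unique(vapply(tracks, function(t) as.character(t$area[1]), ""))
  if (length(areas) > 1)
    stop("all tracks must belong to the same area; got: ",
         paste(areas, collapse = ", "))
  lens <- vapply(tracks, function(t)
    sum(sqrt(diff(t$x)^2 + diff(t$y)^2)), 0)
  rel <- abs(lens - stats::median(lens)) / stats::median(lens)
  if (any(rel > max_length_mismatch))
    stop("round(s) ", paste(which(rel > max_length_mismatch), collapse = ", "),
         " have arc lengths deviating more than ",
         max_length_mismatch * 100, "% from the median")
  m <- 512L  # common parameterisation
  rs <- lapply(tracks, function(t) {
    seg <- sqrt(diff(t$x)^2 + diff(t$y)^2)
    s <- c(0, cumsum(seg))
    at <- seq(0, s[length(s)], length.out = m)
    cbind(stats::approx(s, t$x, xout = at, ties = "ordered")$y,
          stats::approx(s, t$y, xout = at, ties = "ordered")$y)
  })
  mean_path <- Reduce(`+`, rs) / length(rs)
  resample_polyline(mean_path, spacing)
}

#' Aggregate preprocessed samples onto route points
#'
#' For every route point, pools all samples (across every round) within
#' `radius` meters (inclusive at the boundary) and computes the maximum,
#' minimum, mean and standard deviation of the local concentration. The sd
#' uses the population form (denominator n) as a descriptive statistic of
#' the pooled samples. Points with no contributing sample are flagged
#' missing.
#'
#' @param route matrix of route points from [build_ideal_route()].
#' @param tracks list of preprocessed tracks (column `pm25_local`).
#' @param radius buffer radius in meters (> 0); default 25.
#' @return a `route_points` data frame: `x`, `y`, `pm_max`, `pm_min`,
#'   `pm_mean`, `pm_sd`, `n_contributing`.
#' @export
aggregate_to_route <- function(route, tracks, radius = 25) {
  if (radius <= 0) stop("radius must be > 0")
  all_s <- do.call(rbind, lapply(tracks, function(t)
    data.frame(x = t$x, y = t$y, v = t$pm25_local)))
  n <- nrow(route)
  out <- data.frame(x = route[, 1], y = route[, 2],
                    pm_max = NA_real_, pm_min = NA_real_,
                    pm_mean = NA_real_, pm_sd = NA_real_,
                    n_contributing = 0L)
  for (i in seq_len(n)) {
    d2 <- (all_s$x - route[i, 1])^2 + (all_s$y - route[i, 2])^2
    v <- all_s$v[d2 <= radius^2]
    if (length(v) == 0) next
    out$pm_max[i] <- max(v)
    out$pm_min[i] <- min(v)
    out$pm_mean[i] <- mean(v)
    out$pm_sd[i] <- sqrt(mean((v - mean(v))^2))
    out$n_contributing[i] <- length(v)
  }
  class(out) <- c("route_points", "data.frame")
  out
}
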