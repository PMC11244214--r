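#' Buffer radii specification
#'
#' @param radii strictly increasing positive radii in meters. The default is
#'   the ten-ring scheme 25-1000 m used throughout the package.
#' @return numeric vector of radii (classed for printing).
#' @export
buffer_spec <- function(radii = c(25, 50, 75, 100, 150, 200, 250, 500, 750, 1000)) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing and positive")
  radii
}

#' Continuous buffer statistics at one center
#'
#' Maximum, minimum and mean over all cells whose centers lie within the
#' Euclidean radius of the center (no-data cells excluded).
#'
#' @param grid a [lur_grid] (continuous).
#' @param center numeric `c(x, y)`, inside the grid extent.
#' @param radius buffer radius, meters.
#' @return named numeric `c(max, min, mean)`; `NA`s when the buffer holds no
#'   valid cell.
#' @export
continuous_buffer_stats <- function(grid, center, radius) {
  if (!inside_extent(grid, center[1], center[2]))
    stop("center outside the grid extent")
  m <- cpp_buffer_continuous(grid$values, center[1], center[2], radius,
                             grid$xmin, grid$ymin, grid$res)
  c(max = m[1, 1], min = m[1, 2], mean = m[1, 3])
}

#' Categorical buffer statistics at one center
#'
#' `cat_max` is the modal code among buffer cells; `cat_min` the least
#' frequent among codes actually present (absent codes do not compete).
#' Frequency ties go to the smaller code.
#'
#' @inheritParams continuous_buffer_stats
#' @return named numeric `c(cat_max, cat_min)`.
#' @export
categorical_buffer_stats <- function(grid, center, radius) {
  if (!inside_extent(grid, center[1], center[2]))
    stop("center outside the grid extent")
  m <- cpp_buffer_categorical(grid$values, center[1], center[2], radius,
                              grid$xmin, grid$ymin, grid$res)
  c(cat_max = m[1, 1], cat_min = m[1, 2])
}

#' Build the named predictor table
#'
#' Computes buffer statistics of every layer at every point, producing
#' columns named `name_stat_buffer` (e.g. `DTV_min_750`,
#' `LCZ_cat_max_100`): three columns per radius for continuous layers
#' (`max`, `min`, `mean`), two for categorical layers (`cat_max`,
#' `cat_min`). Column order is deterministic: layer order, then statistic,
#' then radius. Rows with any missing predictor are dropped; predictors are
#' left unscaled (random forests are insensitive to monotone scaling).
#'
#' @param points data frame with `x`, `y`; route points may carry the
#'   per-point maximum local concentration in `pm_max`, which becomes the
#'   modelling target. Station tables may omit it.
#' @param grids named list of [lur_grid] layers sharing one grid.
#' @param radii buffer radii from [buffer_spec()].
#' @return a `lur_features` data frame whose first column is `target` when
#'   present; attributes: `codebook` (categorical name -> code set),
#'   `feature_names`, `n_dropped`.
#' @export
build_feature_table <- function(points, grids, radii = buffer_spec()) {
  res <- grids[[1]]$res
  if (res > min(radii) / 2)
    stop("grid resolution must be <= smallest radius / 2 (got ", res, ")")
  x <- points$x; y <- points$y
  cols <- list()
  for (g in grids) {
    stats_for <- if (g$kind == "continuous") c("max", "min", "mean")
                 else c("cat_max", "cat_min")
    for (r in radii) {
      m <- if (g$kind == "continuous")
        cpp_buffer_continuous(g$values, x, y, r, g$xmin, g$ymin, res)
      else
        cpp_buffer_categorical(g$values, x, y, r, g$xmin, g$ymin, res)
      for (s in seq_along(stats_for)) {
        nm <- paste(g$name, stats_for[s], r, sep = "_")
        if (nm %in% names(cols)) stop("column name collision: ", nm)
        cols[[nm]] <- m[, s]
      }
    }
  }
  # reorder: layer, then statistic, then radius
  ord <- unlist(lapply(grids, function(g) {
    stats_for <- if (g$kind == "continuous") c("max", "min", "mean")
                 else c("cat_max", "cat_min")
    as.vector(vapply(stats_for, function(s)
      paste(g$name, s, radii, sep = "_"), character(length(radii))))
  }))
  cols <- cols[ord]
  tab <- as.data.frame(cols, check.names = FALSE)
  has_target <- "pm_max" %in% names(points)
  if (has_target) tab <- cbind(target = points$pm_max, tab)
  keep <- stats::complete.cases(tab)
  dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  codebook <- lapply(Filter(function(g) g$kind == "categorical", grids),
                     `[[`, "codes")
  attr(tab, "codebook") <- codebook
  attr(tab, "feature_names") <- ord
  attr(tab, "n_dropped") <- dropped
  attr(tab, "kept_rows") <- which(keep)
  class(tab) <- c("lur_features", "data.frame")
  tab
}

# feature columns (everything except the target)
feature_names <- function(table) {
  setdiff(names(table), "target")
}
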