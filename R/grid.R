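#' Regular raster grid on a projected plane
#'
#' Minimal raster container used for all predictor layers: a numeric matrix
#' of cell values on a regular grid in projected planar coordinates (meters).
#' Row `i`, column `j` holds the cell whose center is at
#' `x = xmin + (j - 0.5) * res`, `y = ymin + (i - 0.5) * res`.
#'
#' @param values numeric matrix of cell values (rows index y, columns x).
#' @param xmin,ymin coordinates of the grid origin (lower-left corner), m.
#' @param res cell size in meters (square cells).
#' @param name layer name, e.g. `"LAI"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param codes integer code set for categorical layers, else `NULL`.
#' @return an object of class `lur_grid`.
#' @export
lur_grid <- function(values, xmin = 0, ymin = 0, res = 1,
                     name = "layer", kind = c("continuous", "categorical"),
                     codes = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), res > 0)
  if (kind == "categorical") {
    if (is.null(codes)) codes <- sort(unique(as.integer(values)))
    codes <- as.integer(codes)
  }
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res,
                 name = name, kind = kind, codes = codes),
            class = "lur_grid")
}

#' @export
print.lur_grid <- function(x, ...) {
  cat(sprintf("<lur_grid> %s (%s): %d x %d cells, res %g m, origin (%g, %g)\n",
              x$name, x$kind, nrow(x$values), ncol(x$values), x$res,
              x$xmin, x$ymin))
  invisible(x)
}

# extent as c(xmin, xmax, ymin, ymax)
grid_extent <- function(g) {
  c(g$xmin, g$xmin + ncol(g$values) * g$res,
    g$ymin, g$ymin + nrow(g$values) * g$res)
}

inside_extent <- function(g, x, y) {
  e <- grid_extent(g)
  x >= e[1] & x <= e[2] & y >= e[3] & y <= e[4]
}

# value of the cell containing each (x, y); vectors recycled per element
grid_value_at <- function(g, x, y) {
  j <- pmin(pmax(floor((x - g$xmin) / g$res) + 1, 1), ncol(g$values))
  i <- pmin(pmax(floor((y - g$ymin) / g$res) + 1, 1), nrow(g$values))
  g$values[cbind(i, j)]
}

#' Read and write grids as gridded CSV
#'
#' The on-disk format is a plain CSV with columns `x`, `y`, `value` (cell
#' centers) plus a commented header carrying the grid metadata, so layers
#' remain diffable text.
#'
#' @param g a [lur_grid].
#' @param path file path.
#' @return `read_grid_csv` returns a [lur_grid]; `write_grid_csv` returns
#'   `path` invisibly.
#' @export
write_grid_csv <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lur_grid name=%s kind=%s codes=%s xmin=%g ymin=%g res=%g nx=%d ny=%d",
                     g$name, g$kind,
                     if (is.null(g$codes)) "" else paste(g$codes, collapse = ";"),
                     g$xmin, g$ymin, g$res, ncol(g$values), nrow(g$values)), con)
  nx <- ncol(g$values); ny <- nrow(g$values)
  xy <- expand.grid(j = seq_len(nx), i = seq_len(ny))
  df <- data.frame(x = g$xmin + (xy$j - 0.5) * g$res,
                   y = g$ymin + (xy$i - 0.5) * g$res,
                   value = g$values[cbind(xy$i, xy$j)])
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# lur_grid"))
    stop("not a lur_grid CSV: ", path)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]*", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  nx <- as.integer(meta[["nx"]]); ny <- as.integer(meta[["ny"]])
  vals <- matrix(df$value, nrow = ny, ncol = nx, byrow = TRUE)
  codes <- if (nzchar(meta[["codes"]]))
    as.integer(strsplit(meta[["codes"]], ";")[[1]]) else NULL
  lur_grid(vals, xmin = as.numeric(meta[["xmin"]]),
           ymin = as.numeric(meta[["ymin"]]), res = as.numeric(meta[["res"]]),
           name = meta[["name"]], kind = meta[["kind"]], codes = codes)
}
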