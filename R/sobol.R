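## Variance-based (Sobol') global sensitivity analysis: quasi-random
## sampling, the Saltelli radial design, and first-/total-order index
## estimation.

# cache for the Joe-Kuo direction-number table
.lurf_env <- new.env(parent = emptyenv())

load_directions <- function() {
  if (!is.null(.lurf_env$poly)) return(invisible())
  path <- system.file("extdata", "joe_kuo_directions.txt", package = "lurf")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), " +")
  poly <- vapply(parts, function(p) as.integer(p[1]), 1L)
  maxdeg <- max(lengths(parts)) - 1L
  minit <- matrix(0L, length(parts), maxdeg)
  for (i in seq_along(parts)) {
    m <- as.integer(parts[[i]][-1])
    minit[i, seq_along(m)] <- m
  }
  .lurf_env$poly <- poly
  .lurf_env$minit <- minit
  invisible()
}

#' Sobol' low-discrepancy sequence
#'
#' Quasi-random points in the unit hypercube, generated from the Joe & Kuo
#' (2008) direction numbers in Gray-code order. With `scramble = TRUE` a
#' seeded random digital shift (XOR with a 30-bit integer per dimension) is
#' applied, which randomizes the sequence while preserving its
#' low-discrepancy structure.
#'
#' @param n number of points.
#' @param d dimension (up to 640).
#' @param scramble apply a random digital shift.
#' @param seed seed for the shift.
#' @return an `n x d` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, scramble = TRUE, seed = 1) {
  load_directions()
  if (d > length(.lurf_env$poly))
    stop("dimension exceeds the shipped direction-number table (",
         length(.lurf_env$poly), ")")
  shift <- if (scramble)
    with_seed(seed, as.integer(floor(stats::runif(d) * 2^30)))
  else integer(d)
  cpp_sobol_points(as.integer(n), as.integer(d),
                   .lurf_env$poly, .lurf_env$minit, shift)
}

#' Parameter space of a feature table
#'
#' Uniform bounds per feature from the observed column minima and maxima.
#' Constant-range columns cannot be sampled and are dropped with a warning
#' (they are listed in the result so reports can account for them).
#' Categorical features (identified through the table's codebook) keep their
#' code sets for later rounding.
#'
#' @param table a `lur_features` table.
#' @return a `parameter_space`: `names`, `bounds` (2 x D), `kind`, `codes`,
#'   `dropped`, `D`.
#' @export
build_parameter_space <- function(table) {
  feats <- feature_names(table)
  if (nrow(table) == 0 || length(feats) == 0) stop("empty feature table")
  lo <- vapply(table[feats], min, 0)
  hi <- vapply(table[feats], max, 0)
  keep <- hi > lo
  if (!any(keep)) stop("all feature columns are constant")
  if (any(!keep))
    warning(sum(!keep), " constant column(s) excluded from the parameter space: ",
            paste(head(feats[!keep], 5), collapse = ", "))
  codebook <- attr(table, "codebook") %||% list()
  base_of <- sub("_(max|min|mean|cat_max|cat_min)_[0-9]+$", "", feats)
  kind <- ifelse(base_of %in% names(codebook) & grepl("_cat_(max|min)_", feats),
                 "categorical", "continuous")
  codes <- lapply(seq_along(feats), function(i)
    if (kind[i] == "categorical") codebook[[base_of[i]]] else NULL)
  structure(list(names = feats[keep],
                 bounds = rbind(lo = lo[keep], hi = hi[keep]),
                 kind = kind[keep], codes = codes[keep],
                 dropped = feats[!keep],
                 constants = stats::setNames(lo[!keep], feats[!keep]),
                 D = sum(keep)),
            class = "parameter_space")
}

#' Total evaluations of a Saltelli design
#'
#' `S = N * (D + 2)`: the two quasi-random base matrices A and B plus the D
#' cross matrices AB_i.
#'
#' @param N base sample count (must be a power of two).
#' @param D number of sampled features.
#' @return integer S.
#' @export
sobol_design_size <- function(N, D) {
  check_power_of_two(N)
  as.integer(N) * (as.integer(D) + 2L)
}

check_power_of_two <- function(N) {
  if (!is_power_of_two(N))
    stop("N must be a power of two; next valid value: 2^",
         ceiling(log2(N)), " = ", 2^ceiling(log2(N)))
  invisible(N)
}

#' Saltelli sample over a parameter space
#'
#' Draws two independent quasi-random base matrices A and B from a Sobol'
#' sequence in 2D dimensions, scaled to the per-feature bounds, and forms
#' the D radial cross matrices AB_i (A with column i replaced from B). Rows
#' are ordered A, AB_1 ... AB_D, B, giving `N * (D + 2)` evaluations.
#'
#' @param space a [build_parameter_space()] result.
#' @param N base sample count; must be a power of two.
#' @param seed scrambling seed.
#' @param scramble randomize the underlying sequence (digital shift).
#' @return a `sobol_design`: `matrix` (S x D, feature column names), `N`,
#'   `D`, `space`, `seed`.
#' @export
saltelli_sample <- function(space, N = 2048, seed = 1, scramble = TRUE) {
  check_power_of_two(N)
  D <- space$D
  base <- sobol_sequence(N, 2 * D, scramble = scramble, seed = seed)
  lo <- space$bounds["lo", ]; hi <- space$bounds["hi", ]
  A <- sweep(sweep(base[, 1:D, drop = FALSE], 2, hi - lo, `*`), 2, lo, `+`)
  B <- sweep(sweep(base[, D + 1:D, drop = FALSE], 2, hi - lo, `*`), 2, lo, `+`)
  S <- matrix(NA_real_, N * (D + 2), D)
  S[1:N, ] <- A
  for (i in seq_len(D)) {
    ABi <- A
    ABi[, i] <- B[, i]
    S[i * N + 1:N, ] <- ABi
  }
  S[(D + 1) * N + 1:N, ] <- B
  colnames(S) <- space$names
  structure(list(matrix = S, N = as.integer(N), D = D, space = space,
                 seed = seed),
            class = "sobol_design")
}

#' @export
print.sobol_design <- function(x, ...) {
  cat(sprintf("<sobol_design> N = %d, D = %d, %d evaluations (A, AB_i, B)\n",
              x$N, x$D, nrow(x$matrix)))
  invisible(x)
}

#' Round categorical design columns to valid codes
#'
#' Sampled categorical columns are rounded half-away-from-zero to the
#' nearest integer, then clamped to the nearest valid code of the layer.
#'
#' @param design a `sobol_design`.
#' @param space the matching `parameter_space` (defaults to the design's).
#' @return the design with categorical columns mapped onto their code sets.
#' @export
round_categoricals <- function(design, space = design$space) {
  m <- design$matrix
  for (i in which(space$kind == "categorical")) {
    v <- round_half_away(m[, i])
    codes <- sort(space$codes[[i]])
    # clamp to nearest valid code
    idx <- findInterval(v, codes, all.inside = TRUE)
    low <- codes[idx]; high <- codes[pmin(idx + 1L, length(codes))]
    m[, i] <- ifelse(abs(v - low) <= abs(high - v), low, high)
  }
  design$matrix <- m
  design
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate first- and total-order Sobol' indices
#'
#' First-order indices use the Saltelli (2010) estimator
#' `FOS_i = mean(fB * (fAB_i - fA)) / V`; total-order indices the Jansen
#' (1999) estimator `TOS_i = mean((fA - fAB_i)^2) / (2 V)`, both normalized
#' by the sample variance `V` of the pooled A and B evaluations. If the
#' model output is constant all indices are zero (with a warning). Negative
#' estimates (possible at finite N) are reported as-is.
#'
#' @param y model evaluations over a Saltelli design, length `N * (D + 2)`,
#'   in the design's row order.
#' @param D,N design dimensions.
#' @return list with `fos` and `tos`, each length D.
#' @export
estimate_indices <- function(y, D, N) {
  if (length(y) != N * (D + 2)) stop("evaluations length must be N * (D + 2)")
  if (any(!is.finite(y))) stop("evaluations must be finite")
  fA <- y[1:N]
  fB <- y[(D + 1) * N + 1:N]
  V <- stats::var(c(fA, fB))
  if (V == 0) {
    warning("zero output variance; all indices are 0")
    return(list(fos = numeric(D), tos = numeric(D)))
  }
  fos <- numeric(D); tos <- numeric(D)
  for (i in seq_len(D)) {
    fABi <- y[i * N + 1:N]
    fos[i] <- mean(fB * (fABi - fA)) / V
    tos[i] <- mean((fA - fABi)^2) / (2 * V)
  }
  list(fos = fos, tos = tos)
}

#' Sensitivity indices aggregated over a model ensemble
#'
#' Evaluates every fitted forest of the ensemble on the design, estimates
#' FOS/TOS per model, and reports the across-model mean and spread (sd).
#' With `rescramble = TRUE` each model is evaluated on a freshly scrambled
#' design over the same space, so averaging over models also averages over
#' sampling error of the design.
#'
#' @param ensemble a [lur_ensemble].
#' @param design a `sobol_design` whose columns cover the ensemble features.
#' @param max_models cap on how many ensemble members to evaluate (all by
#'   default).
#' @param rescramble re-scramble the design per model.
#' @return a `sensitivity_result`: data frame `summary` (feature, mean_fos,
#'   mean_tos, sd_fos, sd_tos) plus matrices `fos`, `tos` (feature x model).
#' @export
aggregate_over_ensemble <- function(ensemble, design, max_models = NULL,
                                    rescramble = FALSE) {
  if (length(ensemble$models) < 1) stop("ensemble has no fitted models")
  models <- ensemble$models
  if (!is.null(max_models)) models <- models[seq_len(min(max_models, length(models)))]
  D <- design$D; N <- design$N
  fos <- matrix(NA_real_, D, length(models))
  tos <- matrix(NA_real_, D, length(models))
  for (k in seq_along(models)) {
    dk <- if (rescramble && k > 1)
      round_categoricals(saltelli_sample(design$space, N,
                                         seed = design$seed + 7919L * k))
    else design
    xk <- dk$matrix
    # constant columns are not sampled; re-attach them at their fixed value
    # so the forests see their full feature set
    cst <- dk$space$constants
    if (length(cst) > 0)
      xk <- cbind(xk, matrix(rep(cst, each = nrow(xk)), nrow(xk),
                             dimnames = list(NULL, names(cst))))
    yk <- predict(models[[k]], xk, num.threads = 1)$predictions
    est <- estimate_indices(yk, D, N)
    fos[, k] <- est$fos
    tos[, k] <- est$tos
  }
  rownames(fos) <- rownames(tos) <- design$space$names
  if (any(fos < -0.05, na.rm = TRUE))
    warning("first-order index estimate(s) below -0.05; N may be too small")
  summ <- data.frame(feature = design$space$names,
                     mean_fos = rowMeans(fos), mean_tos = rowMeans(tos),
                     sd_fos = apply(fos, 1, stats::sd),
                     sd_tos = apply(tos, 1, stats::sd))
  structure(list(summary = summ, fos = fos, tos = tos),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d features x %d model runs; top mean FOS:\n",
              nrow(x$fos), ncol(x$fos)))
  s <- x$summary[order(-x$summary$mean_fos), ]
  print(head(s, 8), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Screen features by first-order sensitivity
#'
#' `GSA_parsimonious` keeps the features whose mean FOS is strictly greater
#' than the threshold; `GSA_streets` adds every street-type column of the
#' analysed feature set.
#'
#' @param result a `sensitivity_result`.
#' @param threshold strict lower FOS bound; default 0.01.
#' @param street_pattern regular expression identifying street-type columns.
#' @return list with `gsa_parsimonious` and `gsa_streets` feature sets.
#' @export
screen_features <- function(result, threshold = 0.01,
                            street_pattern = "^street_") {
  s <- result$summary
  sel <- s$feature[s$mean_fos > threshold]
  if (length(sel) == 0)
    warning("no feature exceeds the FOS threshold; empty selection")
  streets <- grep(street_pattern, s$feature, value = TRUE)
  list(gsa_parsimonious = sel,
       gsa_streets = union(sel, streets))
}
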