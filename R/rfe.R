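#' Recursive feature elimination ranking for one run
#'
#' Iteratively fits a random forest on the remaining features and drops the
#' feature(s) with the lowest impurity importance until `n_keep` remain.
#' Survivors receive rank 1; eliminated features are ranked by reversed
#' elimination order (the first feature dropped gets the largest rank).
#' Importance ties are broken by dropping the lexicographically last name.
#'
#' @param table `lur_features` table with `target`.
#' @param seed forest seed for this run.
#' @param n_keep number of surviving features (>= 1, < number of features).
#' @param step how many features to drop per iteration: an integer, or a
#'   fraction in (0, 1) of the remaining features (at least 1; never drops
#'   below `n_keep`). Single-feature steps are the reference behaviour;
#'   fractional steps trade rank resolution for speed on wide tables.
#' @param num_trees trees per forest.
#' @param mtry features tried per split (see [lur_ensemble()]).
#' @return a `rank_record`: named integer vector of ranks (1 = retained
#'   longest), with attribute `seed`.
#' @export
rfe_rank <- function(table, seed = 0, n_keep = 8, step = 1, num_trees = 100,
                     mtry = "third") {
  feats <- feature_names(table)
  if (n_keep < 1) stop("n_keep must be >= 1")
  if (length(feats) < n_keep)
    stop("table must have at least n_keep features")
  y <- table$target
  remaining <- feats
  rk <- stats::setNames(integer(length(feats)), feats)
  next_rank <- length(feats)
  while (length(remaining) > n_keep) {
    fit <- ranger::ranger(x = as.matrix(table[remaining]), y = y,
                          num.trees = num_trees, importance = "impurity",
                          mtry = resolve_mtry(mtry, length(remaining)),
                          seed = as.integer(seed) + 1L, num.threads = 1)
    imp <- ranger::importance(fit)[remaining]
    k <- if (step < 1) max(1L, floor(step * length(remaining))) else as.integer(step)
    k <- min(k, length(remaining) - n_keep)
    # ascending importance; among ties the lexicographically last name
    # is dropped first
    lex <- match(remaining, sort(remaining))
    ord <- order(imp, -lex)
    drop <- remaining[ord[seq_len(k)]]
    for (d in drop) {           # lower importance gets the larger rank
      rk[d] <- next_rank
      next_rank <- next_rank - 1L
    }
    remaining <- setdiff(remaining, drop)
  }
  rk[remaining] <- 1L
  structure(rk, seed = seed, class = c("rank_record", "integer"))
}

# order features along the elimination path: survivors first (rank 1),
# then by increasing rank; lexicographic order inside rank ties
path_order <- function(ranks) {
  nms <- names(ranks)
  nms[order(as.integer(ranks), match(nms, sort(nms)))]
}

# candidate survivor-set sizes to score: all of them on narrow tables,
# a geometric thinning on wide ones
candidate_counts <- function(D, n_min) {
  if (D <= 30) return(seq(D, n_min))
  k <- D
  out <- integer(0)
  while (k > n_min) {
    out <- c(out, k)
    k <- floor(k * 0.7)
  }
  sort(unique(c(out, n_min)), decreasing = TRUE)
}

#' RFE with cross-validated choice of the feature count
#'
#' Computes one elimination path on the table, then scores candidate feature
#' counts along the path by k-fold cross-validated R2; the selected set is
#' the survivor set at the count with the best mean score (ties towards the
#' smaller count).
#'
#' @inheritParams rfe_rank
#' @param folds number of CV folds (>= 2); `folds = n` degenerates to
#'   leave-one-out with a warning.
#' @param counts survivor-set sizes to score; default scores every size on
#'   narrow tables and a geometric thinning on wide ones.
#' @return list with `selected` (feature names), `scores` (data frame of
#'   count and mean CV R2) and `ranks` (rank 1 for the selected set, then
#'   2, 3, ... along the elimination path).
#' @export
rfecv_select <- function(table, seed = 0, folds = 5, step = 1,
                         num_trees = 100, mtry = "third", counts = NULL) {
  n <- nrow(table)
  if (folds < 2) stop("folds must be >= 2")
  if (n < 2 * folds && folds != n) stop("need at least 2 rows per fold")
  if (folds == n) warning("folds equal to n: leave-one-out cross-validation")
  ranks <- rfe_rank(table, seed = seed, n_keep = 1, step = step,
                    num_trees = num_trees, mtry = mtry)
  ord_names <- path_order(ranks)
  D <- length(ord_names)
  if (is.null(counts)) counts <- candidate_counts(D, 1L)
  y <- table$target
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  score <- vapply(counts, function(k) {
    sel <- ord_names[seq_len(k)]
    r2 <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- ranger::ranger(x = as.matrix(table[tr, sel, drop = FALSE]),
                            y = y[tr], num.trees = num_trees,
                            seed = as.integer(seed) + 1L,
                            mtry = resolve_mtry(mtry, length(sel)),
                            num.threads = 1)
      p <- predict(fit, as.matrix(table[!tr, sel, drop = FALSE]),
                   num.threads = 1)$predictions
      obs <- y[!tr]
      sst <- sum((obs - mean(obs))^2)
      # degenerate folds (one row, or constant target) cannot carry R2;
      # score them by negative squared error instead
      if (sst == 0) -mean((p - obs)^2) else 1 - sum((p - obs)^2) / sst
    }, 0)
    mean(r2)
  }, 0)
  k_best <- min(counts[score == max(score)])   # ties -> smaller count
  sel <- ord_names[seq_len(k_best)]
  out_ranks <- stats::setNames(pmax(seq_len(D) - k_best + 1L, 1L), ord_names)
  out_ranks <- out_ranks[names(ranks)]
  class(out_ranks) <- c("rank_record", "integer")
  attr(out_ranks, "seed") <- seed
  list(selected = sel,
       scores = data.frame(count = counts, mean_r2 = score),
       ranks = out_ranks)
}

#' Aggregate ranks over Monte-Carlo runs
#'
#' Computes the mean rank of every feature across runs and retains those
#' with mean rank strictly below the threshold (default 2) - the
#' parsimonious feature set.
#'
#' @param records list of `rank_record`s over different seeds.
#' @param threshold strict upper bound on the mean rank.
#' @return list with `selected` (feature names, table order) and
#'   `mean_rank` (named numeric).
#' @export
aggregate_ranks <- function(records, threshold = 2) {
  if (length(records) < 1) stop("need at least one run")
  feats <- names(records[[1]])
  m <- vapply(records, function(r) as.numeric(r[feats]), numeric(length(feats)))
  if (length(feats) == 1) m <- matrix(m, nrow = 1)
  mean_rank <- stats::setNames(rowMeans(m), feats)
  list(selected = feats[mean_rank < threshold], mean_rank = mean_rank)
}
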