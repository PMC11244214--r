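#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with the campaign
#' defaults: kappa-Koehler parameters, the 5th-percentile trim and
#' background conventions, the 30 s median, the ten buffer radii, the 70/30
#' distribution-preserving split, the Monte-Carlo seed list, the mean-rank
#' (< 2) and FOS (> 0.01) screening thresholds, and the Sobol' base sample
#' count.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param ensemble_seeds seeds of the Monte-Carlo forests.
#' @param mtry features tried per split (see [lur_ensemble()]).
#' @param kappa,rho,trim_fraction,median_window,background_quantile
#'   preprocessing parameters.
#' @param radii buffer radii.
#' @param train_fraction hold-out split fraction.
#' @param rank_threshold mean-rank screening bound (strict).
#' @param fos_threshold FOS screening bound (strict).
#' @param gsa_n Sobol' base sample count (power of two).
#' @param gsa_models how many ensemble members the sensitivity analysis
#'   averages over (`NULL` = all).
#' @param gsa_rescramble re-scramble the design per ensemble member.
#' @param rfe_n_keep surviving feature count for plain RFE.
#' @param rfecv_runs Monte-Carlo repetitions of RFECV feeding the mean-rank
#'   aggregation.
#' @param rfecv_folds CV folds.
#' @param rfe_step elimination step (fraction of remaining features).
#' @param variants model variants to build.
#' @param scene arguments forwarded to [simulate_scene()] (list).
#' @return a `lur_config` list.
#' @export
lur_config <- function(seed = 1,
                       ensemble_seeds = 0:49,
                       mtry = "third",
                       kappa = 0.4, rho = 1.6,
                       trim_fraction = 0.05, median_window = 30,
                       background_quantile = 0.05,
                       radii = buffer_spec(),
                       train_fraction = 0.7,
                       rank_threshold = 2,
                       fos_threshold = 0.01,
                       gsa_n = 256,
                       gsa_models = 12,
                       gsa_rescramble = TRUE,
                       rfe_n_keep = 8,
                       rfecv_runs = 2,
                       rfecv_folds = 3,
                       rfe_step = 0.3,
                       variants = c("baseline", "GSA_parsimonious",
                                    "GSA_streets", "RFE", "RFECV_baseline",
                                    "RFECV_parsimonious"),
                       scene = list()) {
  stopifnot(length(ensemble_seeds) >= 1,
            rank_threshold > 0, fos_threshold >= 0)
  check_power_of_two(gsa_n)
  cfg <- as.list(environment())
  class(cfg) <- "lur_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config[sort(names(config))], f, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full workflow on a synthetic scene
#'
#' Executes simulate -> preprocess -> route -> features -> train baseline ->
#' select (RFE, RFECV, GSA) -> retrain variants -> validate (hold-out and
#' stations). Every stochastic stage is seeded from the configuration, so
#' two runs with the same configuration give identical results. When
#' `out_dir` is given, the key artifacts are written there as CSV/JSON, each
#' stamped with the configuration hash.
#'
#' @param config a [lur_config()].
#' @param out_dir optional output directory for artifacts.
#' @param scene optionally, a pre-built `lur_scene` (skips simulation).
#' @return a list of class `lur_run` with the scene, tables, ensembles,
#'   selections, sensitivity result and validation reports.
#' @export
run_pipeline <- function(config = lur_config(), out_dir = NULL,
                         scene = NULL) {
  hash <- config_hash(config)
  if (is.null(scene))
    scene <- do.call(simulate_scene,
                     c(config$scene, list(seed = config$seed)))

  pre <- lapply(scene$rounds, preprocess_track,
                kappa = config$kappa, rho = config$rho,
                trim_fraction = config$trim_fraction,
                median_window = config$median_window,
                background_quantile = config$background_quantile)

  route <- build_ideal_route(pre)
  rp <- aggregate_to_route(route, pre)
  rp <- rp[rp$n_contributing > 0, , drop = FALSE]

  table <- build_feature_table(rp, scene$grids, config$radii)
  split <- split_table(table, config$train_fraction, seed = config$seed)

  ens <- list()
  ens$baseline <- lur_ensemble(split$train, seeds = config$ensemble_seeds,
                               mtry = config$mtry, model_id = "baseline")

  selections <- list(baseline = feature_names(table),
                     RFECV_baseline = feature_names(table))

  if ("RFE" %in% config$variants) {
    rr <- rfe_rank(split$train, seed = config$seed,
                   n_keep = config$rfe_n_keep, step = config$rfe_step,
                   mtry = config$mtry)
    selections$RFE <- names(rr)[rr == 1L]
  }
  if ("RFECV_parsimonious" %in% config$variants) {
    runs <- lapply(seq_len(config$rfecv_runs), function(r)
      rfecv_select(split$train, seed = config$seed + r - 1,
                   folds = config$rfecv_folds,
                   step = config$rfe_step, mtry = config$mtry)$ranks)
    agg <- aggregate_ranks(runs, threshold = config$rank_threshold)
    sel <- agg$selected
    if (length(sel) == 0) sel <- names(sort(agg$mean_rank))[1]
    selections$RFECV_parsimonious <- sel
    attr(selections$RFECV_parsimonious, "mean_rank") <- agg$mean_rank
  }
  sens <- NULL
  if (any(c("GSA_parsimonious", "GSA_streets") %in% config$variants)) {
    space <- build_parameter_space(split$train)
    design <- round_categoricals(
      saltelli_sample(space, config$gsa_n, seed = config$seed))
    sens <- aggregate_over_ensemble(ens$baseline, design,
                                    max_models = config$gsa_models,
                                    rescramble = config$gsa_rescramble)
    scr <- screen_features(sens, threshold = config$fos_threshold)
    if (length(scr$gsa_parsimonious) == 0)
      scr$gsa_parsimonious <-
        sens$summary$feature[which.max(sens$summary$mean_fos)]
    selections$GSA_parsimonious <- scr$gsa_parsimonious
    selections$GSA_streets <- scr$gsa_streets
  }

  for (v in setdiff(config$variants, "baseline")) {
    sub_train <- split$train[c("target", selections[[v]])]
    attr(sub_train, "codebook") <- attr(table, "codebook")
    class(sub_train) <- class(split$train)
    ens[[v]] <- lur_ensemble(sub_train, seeds = config$ensemble_seeds,
                             mtry = config$mtry, model_id = v)
  }
  ens <- ens[intersect(config$variants, names(ens))]

  hov <- lapply(ens, hov_validate, test = split$test)

  st_points <- data.frame(
    x = vapply(scene$stations, function(s) s$location[["x"]], 0),
    y = vapply(scene$stations, function(s) s$location[["y"]], 0))
  st_features <- build_feature_table(st_points, scene$grids, config$radii)
  n_days <- length(scene$stations[[1]]$dates)
  mdates <- round(seq(1, n_days, length.out = length(scene$rounds)))
  stations <- station_validate(ens, st_features, scene$stations, mdates,
                               q = config$background_quantile)

  run <- structure(list(config = config, config_hash = hash, scene = scene,
                        table = table, split = split, ensembles = ens,
                        selections = selections, sensitivity = sens,
                        hov = hov, stations = stations),
                   class = "lur_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.lur_run <- function(x, ...) {
  cat(sprintf("<lur_run> config %s | %d rows x %d features\n",
              substr(x$config_hash, 1, 8), nrow(x$table),
              length(feature_names(x$table))))
  for (v in names(x$hov)) {
    cat(sprintf("  %-20s %2d features | HOV ", v,
                length(x$selections[[v]])))
    print(x$hov[[v]]$metrics)
  }
  invisible(x)
}

# write key artifacts as text files stamped with the config hash
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# config_hash=", run$config_hash), con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  stamp(as.data.frame(run$table), file.path(out_dir, "feature_table.csv"))
  metrics <- do.call(rbind, lapply(names(run$hov), function(v)
    data.frame(model = v, mode = "hov",
               as.data.frame(unclass(run$hov[[v]]$metrics)))))
  metrics <- rbind(metrics,
    do.call(rbind, lapply(names(run$stations), function(v)
      data.frame(model = v, mode = "stations",
                 as.data.frame(unclass(run$stations[[v]]$metrics))))))
  stamp(metrics, file.path(out_dir, "metrics.csv"))
  sel <- do.call(rbind, lapply(names(run$selections), function(v)
    data.frame(model = v, feature = run$selections[[v]])))
  stamp(sel, file.path(out_dir, "selected_features.csv"))
  if (!is.null(run$sensitivity))
    stamp(run$sensitivity$summary, file.path(out_dir, "sensitivity.csv"))
  per_st <- do.call(rbind, lapply(names(run$stations), function(v)
    data.frame(model = v, run$stations[[v]]$per_station)))
  stamp(per_st, file.path(out_dir, "station_validation.csv"))
  invisible(out_dir)
}
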