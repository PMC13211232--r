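# Experiment orchestration: dataset generation, multi-seed train/evaluate
# runs with validation-calibrated thresholds, sampling-strategy ablation,
# and training-set-size scaling. These functions are the programmatic
# interface; inst/scripts/bedfall wraps them for the shell.

#' Default run configuration
#'
#' Nested configuration for a full experiment run. The default profile is
#' deliberately scaled down (10,000 training / 4,000 test samples) so the
#' whole pipeline runs on one CPU in minutes; pass `n_train = 1e5`,
#' `n_test = 5e4` for the full-scale protocol.
#'
#' @param n_train class-balanced training-set size.
#' @param n_test pose-balanced test-set size (divisible by 4).
#' @param strategy sampling strategy for the training set.
#' @param families model families to train.
#' @param seeds training seeds.
#' @param seed global data-generation seed.
#' @param out_dir output directory for datasets, manifests and reports.
#' @return a `run_config` list.
#' @export
run_config <- function(n_train = 10000, n_test = 4000,
                       strategy = "pose_stratified",
                       families = c("mlp", "cnn", "gcn", "rf", "lstm"),
                       seeds = 41:45, seed = 1, out_dir = tempdir()) {
  world_cfg <- world_config()
  list(
    world = world_cfg,
    sampler = sampler_config(strategy),
    episode = episode_config(),
    label = label_config(sim_timestep = world_cfg$sim_timestep),
    train_cfg = train_config(seeds = seeds),
    n_train = n_train, n_test = n_test,
    split_ratio = 0.9,
    families = families,
    seed = seed,
    out_dir = out_dir
  )
}

#' Generate the training and test datasets of a run
#'
#' Builds the class-balanced training set (with the configured sampling
#' strategy) and the pose-balanced test set (always pose-stratified, seed
#' stream disjoint from training), writes both as CSV together with a run
#' manifest, and reports rejection/balance statistics.
#'
#' @param config a [run_config()].
#' @param with_sequences record LSTM frame sequences as well.
#' @return list with `train`, `test` datasets and `paths`.
#' @export
cmd_generate <- function(config = run_config(), with_sequences = FALSE) {
  world <- build_world(config$world)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  write_manifest(world, manifest_path, extra = list(
    n_train = config$n_train, n_test = config$n_test,
    strategy = config$sampler$strategy, seed = config$seed))
  train <- build_balanced_dataset(
    world, config$sampler, config$episode, config$label,
    n_total = config$n_train, seed = config$seed, stream = 0,
    with_sequences = with_sequences)
  test <- build_pose_balanced_test_set(
    world, sampler_config("pose_stratified"), config$episode, config$label,
    n_test = config$n_test, seed = config$seed,
    with_sequences = with_sequences)
  paths <- list(
    train = file.path(config$out_dir, "train.csv"),
    test = file.path(config$out_dir, "test.csv"),
    manifest = manifest_path)
  write_dataset_csv(train, paths$train)
  write_dataset_csv(test, paths$test)
  message(sprintf(
    "generated %d train (%d attempts) and %d test samples (%d attempts)",
    nrow(train), attr(train, "stats")$attempts,
    nrow(test), attr(test, "stats")$attempts))
  list(train = train, test = test, paths = paths)
}

# train one family across seeds; returns per-seed reports + aggregate
train_eval_family <- function(family, train, val, test, train_cfg,
                              split_seed = 1) {
  is_lstm <- family == "lstm"
  tr <- dataset_features(train, sequences = is_lstm)
  va <- dataset_features(val, sequences = is_lstm)
  te <- dataset_features(test, sequences = is_lstm)
  reports <- list()
  for (s in train_cfg$seeds) {
    model <- build_model(family, seed = s)
    model <- train_model(model, tr$X, tr$y, va$X, va$y, train_cfg)
    tau <- calibrate_threshold(predict(model, va$X), va$c)
    scores <- predict(model, te$X)
    rep <- per_posture_report(scores, te$c, te$y, te$mode, tau)
    rep <- cbind(family = family, seed = s, rep)
    reports[[as.character(s)]] <- rep
  }
  overall <- lapply(reports, function(r) r[r$subgroup == "overall", -(1:2)])
  list(per_seed = do.call(rbind, reports),
       aggregate = cbind(family = family,
                         aggregate_reports(
                           lapply(reports, function(r) r[, -(1:2)]))))
}

#' Train and evaluate the configured model families
#'
#' Splits the training data 9:1 into train/validation, trains every
#' requested family over the configured seeds, calibrates the decision
#' threshold on validation by maximizing F1, evaluates on the pose-balanced
#' test set overall and per posture, and writes per-seed and aggregated
#' (mean +- sd) report CSVs.
#'
#' @param config a [run_config()].
#' @param data optional result of [cmd_generate()] (regenerated otherwise).
#' @return list with `per_seed` and `aggregate` report data.frames.
#' @export
cmd_train_eval <- function(config = run_config(), data = NULL) {
  if (is.null(data)) {
    data <- cmd_generate(config,
                         with_sequences = "lstm" %in% config$families)
  }
  sp <- split_train_val(data$train, config$split_ratio, seed = config$seed)
  per_seed <- list(); aggregate <- list()
  for (family in config$families) {
    message("training family: ", family)
    res <- train_eval_family(family, sp$train, sp$val, data$test,
                             config$train_cfg)
    per_seed[[family]] <- res$per_seed
    aggregate[[family]] <- res$aggregate
  }
  out <- list(per_seed = do.call(rbind, per_seed),
              aggregate = do.call(rbind, aggregate))
  rownames(out$per_seed) <- rownames(out$aggregate) <- NULL
  utils::write.csv(out$per_seed,
                   file.path(config$out_dir, "report_per_seed.csv"),
                   row.names = FALSE)
  utils::write.csv(out$aggregate,
                   file.path(config$out_dir, "report_aggregate.csv"),
                   row.names = FALSE)
  out
}

#' Training-set-size scaling experiment
#'
#' Trains the MLP at each size in `sizes` on nested subsets of one generated
#' pool (the N-sample subset is always contained in every larger subset) and
#' reports AUROC/AUPRC/F1/MSE versus N, one row per (N, seed) plus
#' aggregates.
#'
#' @param config a [run_config()]; `n_train` must be at least `max(sizes)`.
#' @param sizes ascending training-set sizes.
#' @param data optional result of [cmd_generate()].
#' @param family model family to scale (default `"mlp"`).
#' @return list with `per_run` and `aggregate` data.frames.
#' @export
cmd_scaling <- function(config = run_config(), sizes, data = NULL,
                        family = "mlp") {
  stopifnot(!is.unsorted(sizes))
  if (config$n_train < max(sizes)) {
    stop("generated pool is smaller than the largest requested size")
  }
  if (is.null(data)) {
    data <- cmd_generate(config, with_sequences = family == "lstm")
  }
  pool <- data$train
  per_run <- list(); aggregate <- list()
  for (N in sizes) {
    subset_data <- pool[seq_len(N), , drop = FALSE]  # nested by construction
    for (a in c("label_config", "bounds")) {
      attr(subset_data, a) <- attr(pool, a)
    }
    sq <- attr(pool, "sequences")
    if (!is.null(sq)) {
      attr(subset_data, "sequences") <- sq[seq_len(N), , drop = FALSE]
    }
    sp <- split_train_val(subset_data, config$split_ratio,
                          seed = config$seed)
    res <- train_eval_family(family, sp$train, sp$val, data$test,
                             config$train_cfg)
    per_run[[as.character(N)]] <- cbind(n_train = N,
                                        res$per_seed[res$per_seed$subgroup ==
                                                       "overall", ])
    aggregate[[as.character(N)]] <- cbind(
      n_train = N, res$aggregate[res$aggregate$subgroup == "overall", ])
  }
  out <- list(per_run = do.call(rbind, per_run),
              aggregate = do.call(rbind, aggregate))
  rownames(out$per_run) <- rownames(out$aggregate) <- NULL
  utils::write.csv(out$per_run,
                   file.path(config$out_dir, "scaling_per_run.csv"),
                   row.names = FALSE)
  out
}
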