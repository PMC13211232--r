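# Dataset assembly: class-balanced training sets, pose-balanced test sets,
# train/validation splits, and CSV persistence with a metadata header.
#
# CSV schema (42 data columns): mode, c, y, u_00..u_25, v_00..v_12,
# episode_seed; '#'-prefixed metadata lines carry gamma, fps, window, bed
# bounds and the engine/package version. The LSTM sequence matrix (130
# columns per sample, frame-major) travels as the "sequences" attribute and
# in its own CSV.

u_cols <- function() sprintf("u_%02d", 0:25)
v_cols <- function() sprintf("v_%02d", 0:12)

dataset_columns <- function() {
  c("mode", "c", "y", u_cols(), v_cols(), "episode_seed")
}

# deterministic per-episode seed, disjoint across streams, < 2^31 - 1
episode_seed_for <- function(seed, stream, attempt) {
  as.integer((1103515245 * (seed %% 32768) + 777000007 * stream + attempt) %%
               2147483647)
}

new_dataset <- function(rows, label_cfg, bounds, sequences = NULL,
                        stats = NULL) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "label_config") <- label_cfg
  attr(df, "bounds") <- bounds
  if (!is.null(sequences)) {
    attr(df, "sequences") <- do.call(rbind, sequences)
  }
  attr(df, "stats") <- stats
  df
}

episode_record <- function(world, ep, label_cfg, ep_seed, with_sequence) {
  feat <- state_to_features(world, ep$outcome$settled_state)
  y <- risk_label(ep$outcome, label_cfg)
  row <- data.frame(mode = ep$config$mode, c = as.integer(ep$outcome$fell),
                    y = y, stringsAsFactors = FALSE)
  row[u_cols()] <- as.list(feat$u)
  row[v_cols()] <- as.list(feat$v)
  row$episode_seed <- ep_seed
  seq_vec <- if (with_sequence) {
    build_lstm_sequence(ep$outcome$frames, bed_bounds(world))
  } else NULL
  list(row = row, seq = seq_vec)
}

#' Build a class-balanced labelled dataset
#'
#' Runs episodes until exactly `ceiling(n_total/2)` fall and
#' `floor(n_total/2)` non-fall samples are collected; surplus episodes of a
#' filled class are discarded and counted, rejections (drop timeout, floor
#' before bed, instability) are counted per reason.
#'
#' @param world a `bedfall_world`.
#' @param sampler_cfg a [sampler_config()].
#' @param episode_cfg an [episode_config()].
#' @param label_cfg a [label_config()]; its `sim_timestep` must match the
#'   world.
#' @param n_total target sample count N (>= 2).
#' @param seed integer base seed; per-episode seeds are derived from it.
#' @param stream seed-stream id, kept disjoint between train (0) and test
#'   (1) generation.
#' @param with_sequences also record (5, 26) frame sequences for the LSTM.
#' @param max_attempts episode budget before a budget-exhausted error.
#' @return dataset data.frame (see module header) with `stats` attribute.
#' @export
build_balanced_dataset <- function(world, sampler_cfg = sampler_config(),
                                   episode_cfg = episode_config(),
                                   label_cfg = label_config(
                                     sim_timestep = world$config$sim_timestep),
                                   n_total, seed = 1, stream = 0,
                                   with_sequences = FALSE,
                                   max_attempts = 60 * n_total) {
  stopifnot(n_total >= 2)
  quota <- c(fall = ceiling(n_total / 2), nonfall = floor(n_total / 2))
  got <- c(fall = 0L, nonfall = 0L)
  rows <- list(); seqs <- list()
  rejections <- c(floor_before_bed = 0L, timeout = 0L, unstable = 0L)
  surplus <- c(fall = 0L, nonfall = 0L)
  attempt <- 0L
  while (any(got < quota)) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      stop(sprintf(
        "episode budget exhausted: %d attempts, %d/%d fall, %d/%d non-fall",
        max_attempts, got["fall"], quota["fall"], got["nonfall"],
        quota["nonfall"]))
    }
    ep_seed <- episode_seed_for(seed, stream, attempt)
    set.seed(ep_seed)
    ep <- run_episode(world, sampler_cfg, episode_cfg)
    if (!ep$accepted) {
      rejections[ep$reason] <- rejections[ep$reason] + 1L
      next
    }
    cls <- if (ep$outcome$fell) "fall" else "nonfall"
    if (got[cls] >= quota[cls]) {
      surplus[cls] <- surplus[cls] + 1L
      next
    }
    got[cls] <- got[cls] + 1L
    rec <- episode_record(world, ep, label_cfg, ep_seed, with_sequences)
    rows[[length(rows) + 1L]] <- rec$row
    if (with_sequences) seqs[[length(seqs) + 1L]] <- rec$seq
  }
  new_dataset(rows, label_cfg, bed_bounds(world),
              sequences = if (with_sequences) seqs,
              stats = list(attempts = attempt, rejections = rejections,
                           surplus = surplus, quota = quota))
}

#' Build a pose-balanced test set
#'
#' Exactly `n_test / 4` accepted episodes per posture mode, generated with
#' pose-stratified sampling with the mode forced in rotation; mode tags are
#' retained for subgroup evaluation. The class mix within each mode is
#' whatever the dynamics produce (the test set is pose-balanced, not
#' class-balanced).
#'
#' @param world a `bedfall_world`.
#' @param sampler_cfg a pose-stratified [sampler_config()].
#' @param episode_cfg an [episode_config()].
#' @param label_cfg a [label_config()].
#' @param n_test total test-set size, divisible by 4.
#' @param seed base seed (stream 1 is used, disjoint from training).
#' @param with_sequences also record LSTM frame sequences.
#' @param max_attempts episode budget.
#' @return dataset data.frame with `stats` attribute.
#' @export
build_pose_balanced_test_set <- function(world,
                                         sampler_cfg = sampler_config(),
                                         episode_cfg = episode_config(),
                                         label_cfg = label_config(
                                           sim_timestep = world$config$sim_timestep),
                                         n_test, seed = 1,
                                         with_sequences = FALSE,
                                         max_attempts = 60 * n_test) {
  if (n_test %% 4 != 0) stop("n_test must be divisible by 4")
  if (sampler_cfg$strategy != "pose_stratified") {
    stop("the pose-balanced test set requires pose-stratified sampling")
  }
  per_mode <- n_test / 4
  got <- stats::setNames(integer(4), posture_modes())
  rows <- list(); seqs <- list()
  rejections <- c(floor_before_bed = 0L, timeout = 0L, unstable = 0L)
  attempt <- 0L
  while (any(got < per_mode)) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) stop("episode budget exhausted for test set")
    open <- names(got)[got < per_mode]
    mode <- open[1 + (attempt %% length(open))]
    ep_seed <- episode_seed_for(seed, 1, attempt)
    set.seed(ep_seed)
    ep <- run_episode(world, sampler_cfg, episode_cfg, force_mode = mode)
    if (!ep$accepted) {
      rejections[ep$reason] <- rejections[ep$reason] + 1L
      next
    }
    got[mode] <- got[mode] + 1L
    rec <- episode_record(world, ep, label_cfg, ep_seed, with_sequences)
    rows[[length(rows) + 1L]] <- rec$row
    if (with_sequences) seqs[[length(seqs) + 1L]] <- rec$seq
  }
  new_dataset(rows, label_cfg, bed_bounds(world),
              sequences = if (with_sequences) seqs,
              stats = list(attempts = attempt, rejections = rejections,
                           per_mode = per_mode))
}

#' Split a dataset into training and validation subsets
#'
#' Disjoint, exhaustive, seeded shuffle; the training size is
#' `round(ratio * n)`.
#'
#' @param dataset a dataset data.frame.
#' @param ratio training fraction (default 0.9).
#' @param seed shuffle seed.
#' @return list with `train` and `val` datasets (attributes preserved).
#' @export
split_train_val <- function(dataset, ratio = 0.9, seed = 1) {
  n <- nrow(dataset)
  stopifnot(n > 0, ratio > 0, ratio < 1)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(ratio * n)
  take <- function(idx) {
    out <- dataset[idx, , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("label_config", "bounds")) {
      attr(out, a) <- attr(dataset, a)
    }
    sq <- attr(dataset, "sequences")
    if (!is.null(sq)) attr(out, "sequences") <- sq[idx, , drop = FALSE]
    out
  }
  list(train = take(ord[seq_len(n_train)]),
       val = take(ord[setdiff(seq_len(n), seq_len(n_train))]))
}

#' Extract model inputs from a dataset
#'
#' @param dataset a dataset data.frame.
#' @param sequences return the LSTM sequence matrix instead of the 26-D
#'   features.
#' @return list with `X` (matrix), `y`, `c`, `mode`.
#' @export
dataset_features <- function(dataset, sequences = FALSE) {
  X <- if (sequences) {
    sq <- attr(dataset, "sequences")
    if (is.null(sq)) stop("dataset carries no LSTM sequences")
    sq
  } else {
    as.matrix(dataset[, u_cols()])
  }
  list(X = unname(X), y = dataset$y, c = dataset$c, mode = dataset$mode)
}

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a dataset to CSV
#'
#' Full-float-precision, lossless round-trip with [read_dataset_csv()].
#' Metadata ('#'-prefixed comment lines) records gamma, fps, window, bed
#' bounds and the package version.
#'
#' @param dataset a dataset data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  lc <- attr(dataset, "label_config")
  b <- attr(dataset, "bounds")
  meta <- c(
    sprintf("# bedfall dataset v1; package %s",
            as.character(utils::packageVersion("bedfall"))),
    if (!is.null(lc)) sprintf("# gamma=%.17g fps=%.17g window=%.17g",
                              lc$gamma, lc$fps, lc$window),
    if (!is.null(b)) sprintf(
      "# bed_bounds x_min=%.17g x_max=%.17g y_min=%.17g y_max=%.17g",
      b$x_min, b$x_max, b$y_min, b$y_max)
  )
  header <- paste(dataset_columns(), collapse = ",")
  num_cols <- setdiff(dataset_columns(), c("mode", "c", "episode_seed"))
  body_cols <- c(
    list(ifelse(is.na(dataset$mode), "NA", dataset$mode),
         as.character(dataset$c)),
    lapply(dataset[num_cols[1:27]], fmt_full),      # y, u_00..u_25
    lapply(dataset[v_cols()], as.character),
    list(as.character(dataset$episode_seed))
  )
  writeLines(c(meta, header, do.call(paste, c(body_cols, sep = ","))), path)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV path.
#' @return dataset data.frame with `label_config` and `bounds` attributes
#'   restored from the metadata lines.
#' @export
read_dataset_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, dataset_columns())) {
    stop("parse error at line ", which(lines == body[1]),
         ": header does not match the dataset schema")
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c(mode = "character"),
                        na.strings = "NA")
  nf <- which(lengths(strsplit(body[-1], ",", fixed = TRUE)) !=
                length(header))
  if (length(nf) > 0) {
    stop("parse error at line ", nf[1] + length(meta) + 1,
         ": wrong field count")
  }
  gm <- regmatches(meta, regexec(
    "gamma=([-0-9.eg+]+) fps=([-0-9.e+]+) window=([-0-9.e+]+)", meta))
  gm <- gm[lengths(gm) == 4]
  if (length(gm) > 0) {
    v <- as.numeric(gm[[1]][2:4])
    attr(df, "label_config") <- label_config(fps = v[2], gamma = v[1],
                                             window = v[3])
  }
  bm <- regmatches(meta, regexec(paste0(
    "x_min=([-0-9.e+]+) x_max=([-0-9.e+]+) ",
    "y_min=([-0-9.e+]+) y_max=([-0-9.e+]+)"), meta))
  bm <- bm[lengths(bm) == 5]
  if (length(bm) > 0) {
    v <- as.numeric(bm[[1]][2:5])
    attr(df, "bounds") <- list(x_min = v[1], x_max = v[2], y_min = v[3],
                               y_max = v[4])
  }
  df
}

#' Write/read the LSTM sequence matrix
#'
#' @param dataset a dataset with a `sequences` attribute.
#' @param path CSV path.
#' @return `path` / the sequence matrix.
#' @export
write_sequences_csv <- function(dataset, path) {
  sq <- attr(dataset, "sequences")
  if (is.null(sq)) stop("dataset carries no LSTM sequences")
  header <- paste(sprintf("s_%03d", seq_len(ncol(sq)) - 1), collapse = ",")
  rows <- apply(sq, 1, function(r) paste(fmt_full(r), collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @export
read_sequences_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
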