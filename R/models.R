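# Risk regression model families: MLP (primary), 1D CNN, GCN, random forest,
# and LSTM, all trained to regress the continuous risk label with the MSE
# loss under a shared training protocol.

#' Shared training configuration
#'
#' @param learning_rate initial Adam learning rate (default 1e-3).
#' @param batch_size mini-batch size (default 512).
#' @param max_epochs maximum training epochs (default 50).
#' @param val_fraction validation split fraction used when a validation set
#'   is carved internally (default 0.1).
#' @param seeds the random seeds of the multi-seed protocol
#'   (default 41:45); every reported metric is the mean +- sd over them.
#' @param dropout dropout probability for the neural families (default 0.1).
#' @return a `train_config` list. The loss is always mean squared error and
#'   the optimizer Adam with default moment parameters (0.9, 0.999).
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 512,
                         max_epochs = 50, val_fraction = 0.1,
                         seeds = 41:45, dropout = 0.1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, val_fraction = val_fraction,
                 seeds = seeds, dropout = dropout),
            class = "train_config")
}

#' Model specification
#'
#' Architectures are fixed per family: MLP 26-256-128-1 (ReLU, dropout 0.1);
#' CNN on the 2 x 13 tensor with two length-3 convolutions (2-32-64), global
#' average pooling and a 64-64-1 head; GCN with 13 nodes x 2 features on the
#' fixed skeleton graph (self-loops, symmetric normalized adjacency), two
#' 64-dim layers and an 832-256-128-64-1 head; RF with 300 trees and
#' unlimited depth; LSTM on (5, 26) frame sequences with one 64-dim layer
#' and a 64-1 head on the last hidden state.
#'
#' @param family one of `"mlp"`, `"cnn"`, `"gcn"`, `"rf"`, `"lstm"`.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("mlp", "cnn", "gcn", "rf", "lstm")) {
  family <- match.arg(family)
  structure(list(family = family), class = "model_spec")
}

#' Build an untrained model
#'
#' @param spec a [model_spec()] (or a family name).
#' @param seed integer seed for the parameter initialization.
#' @return an untrained `bedfall_model`.
#' @export
build_model <- function(spec, seed = 41) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  aux <- NULL
  params <- switch(spec$family,
    mlp = mlp_init(),
    cnn = cnn_init(),
    gcn = { g <- gcn_init(); aux <- g[c("K2", "K64")]; g$params },
    lstm = lstm_init(),
    rf = NULL)
  structure(list(family = spec$family, spec = spec, seed = seed,
                 params = params, aux = aux, trained = FALSE,
                 history = NULL, selected_epoch = NA_integer_),
            class = "bedfall_model")
}

#' Number of trainable parameters
#'
#' @param model a `bedfall_model` (neural families).
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "bedfall_model"))
  if (is.null(model$params)) stop("random forests have no parameter count")
  sum(vapply(model$params, length, integer(1)))
}

model_fwd_bwd <- function(model, config) {
  dp <- config$dropout
  switch(model$family,
    mlp = list(
      fwd = function(p, X, train) mlp_forward(p, X, dp, train),
      bwd = function(p, cache, dout) mlp_backward(p, cache, dout)),
    cnn = list(
      fwd = function(p, X, train) cnn_forward(p, X, dp, train),
      bwd = function(p, cache, dout) cnn_backward(p, cache, dout)),
    gcn = list(
      fwd = function(p, X, train) gcn_forward(p, X, model$aux, dp, train),
      bwd = function(p, cache, dout) gcn_backward(p, cache, dout, model$aux)),
    lstm = list(
      fwd = function(p, X, train) lstm_forward(p, X, dp, train),
      bwd = function(p, cache, dout) lstm_backward(p, cache, dout)),
    stop("family has no gradient trainer: ", model$family))
}

#' Train a model on feature/label matrices
#'
#' Minimizes mini-batch MSE with Adam for at most `max_epochs` epochs,
#' records per-epoch train/validation loss, and returns the checkpoint with
#' minimum validation loss. Dropout is active during training only;
#' inference is deterministic. The test set is never consulted.
#'
#' @param model an untrained `bedfall_model` from [build_model()].
#' @param X training feature matrix (n x 26; n x 130 for the LSTM).
#' @param y training labels.
#' @param Xval,yval validation split (same schema).
#' @param config a [train_config()].
#' @return the trained `bedfall_model` with `history` and `selected_epoch`.
#' @export
train_model <- function(model, X, y, Xval, yval, config = train_config()) {
  stopifnot(inherits(model, "bedfall_model"))
  if (model$family == "rf") {
    return(train_rf_xy(model, X, y))
  }
  fb <- model_fwd_bwd(model, config)
  set.seed(model$seed)
  fit <- train_loop(model$params, fb$fwd, fb$bwd, X, y, Xval, yval, config)
  model$params <- fit$params
  model$history <- fit$history
  model$selected_epoch <- fit$selected_epoch
  model$trained <- TRUE
  model
}

train_rf_xy <- function(model, X, y) {
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = 300, mtry = ncol(X), min.node.size = 1,
    seed = model$seed, num.threads = 1)
  model$rf_fit <- fit
  model$trained <- TRUE
  model
}

#' Train the random-forest family
#'
#' A 300-tree regression forest on (u, y) with unlimited depth, grown with
#' all features available at each split.
#'
#' @param X feature matrix (n x 26).
#' @param y continuous labels.
#' @param seed forest seed.
#' @return a trained `bedfall_model` with family `"rf"`.
#' @export
train_rf <- function(X, y, seed = 41) {
  train_rf_xy(build_model("rf", seed), X, y)
}

#' Predict risk scores
#'
#' Deterministic inference (dropout disabled): repeated calls and batched
#' versus per-sample calls agree exactly.
#'
#' @param object a trained (or untrained neural) `bedfall_model`.
#' @param X feature matrix matching the family's input shape.
#' @param ... unused.
#' @return numeric vector of unclipped risk scores.
#' @export
predict.bedfall_model <- function(object, X, ...) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  expected <- if (object$family == "lstm") 130L else 26L
  if (ncol(X) != expected) {
    stop(sprintf("%s input must have %d columns, got %d",
                 object$family, expected, ncol(X)))
  }
  switch(object$family,
    rf = {
      if (!isTRUE(object$trained)) stop("random forest is not trained")
      unname(predict(object$rf_fit, data = as.data.frame(X),
                     num.threads = 1)$predictions)
    },
    mlp = mlp_forward(object$params, X)$pred,
    cnn = cnn_forward(object$params, X)$pred,
    gcn = gcn_forward(object$params, X, object$aux)$pred,
    lstm = lstm_forward(object$params, X)$pred)
}

#' Build an LSTM input sequence from episode frames
#'
#' Takes the raw planar skeleton snapshots recorded on the 30 fps grid from
#' the episode start (frames 0-4), normalizes each frame to the bed bounds,
#' and flattens to one (5, 26) sample stored as a length-130 vector
#' (frame-major). Episodes that fall before frame 4 are padded upstream by
#' repeating the last pre-fall frame.
#'
#' @param frames n_frames x 26 matrix of raw planar coordinates
#'   (x1, y1, ..., x13, y13 per row).
#' @param bounds bed bounds used for normalization.
#' @param n_frames number of frames in a sequence (default 5).
#' @return numeric vector of length `26 * n_frames`.
#' @export
build_lstm_sequence <- function(frames, bounds, n_frames = 5) {
  stopifnot(nrow(frames) >= n_frames, ncol(frames) == 26)
  as.vector(vapply(seq_len(n_frames), function(f) {
    frame_to_features(frames[f, ], bounds)
  }, numeric(26)))
}
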