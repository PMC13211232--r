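# Minimal neural-network machinery: dense/conv/graph/recurrent forward and
# backward passes written on top of BLAS matrix products, with inverted
# dropout and Adam. Each family supplies forward(params, X, masks) and
# backward(params, cache, dout); the shared trainer does batching, the MSE
# loss, per-epoch validation, and min-validation-loss checkpoint selection.
# All randomness (init, shuffling, dropout) uses R's RNG so runs are
# reproducible from a seed.

relu <- function(x) (x > 0) * x
sigm <- function(x) 1 / (1 + exp(-x))

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

unif_init <- function(n_in, n_out, scale) {
  matrix(runif(n_in * n_out, -scale, scale), n_in, n_out)
}

drop_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((runif(n * m) >= p) / (1 - p), n, m)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

addb <- function(Z, b) sweep(Z, 2, b, "+")

## ---- MLP: 26 -> 256 -> 128 -> 1, ReLU, dropout after hidden layers ----

mlp_init <- function(dims = c(26, 256, 128, 1)) {
  list(W1 = he_init(dims[1], dims[2]), b1 = numeric(dims[2]),
       W2 = he_init(dims[2], dims[3]), b2 = numeric(dims[3]),
       W3 = he_init(dims[3], dims[4]), b3 = numeric(dims[4]))
}

mlp_forward <- function(p, X, dropout = 0, train = FALSE) {
  m1 <- if (train) drop_mask(nrow(X), ncol(p$W1), dropout) else NULL
  m2 <- if (train) drop_mask(nrow(X), ncol(p$W2), dropout) else NULL
  Z1 <- addb(X %*% p$W1, p$b1); A1 <- apply_mask(relu(Z1), m1)
  Z2 <- addb(A1 %*% p$W2, p$b2); A2 <- apply_mask(relu(Z2), m2)
  out <- addb(A2 %*% p$W3, p$b3)
  list(pred = drop(out),
       cache = list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
                    m1 = m1, m2 = m2))
}

mlp_backward <- function(p, cache, dout) {
  dout <- matrix(dout, ncol = 1)
  dW3 <- crossprod(cache$A2, dout); db3 <- colSums(dout)
  dA2 <- apply_mask(dout %*% t(p$W3), cache$m2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$A1, dZ2); db2 <- colSums(dZ2)
  dA1 <- apply_mask(dZ2 %*% t(p$W2), cache$m1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$X, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

## ---- CNN: input 2 x 13, Conv1d(2,32,3) -> ReLU -> Conv1d(32,64,3) ->
## ReLU -> global AvgPool -> head 64 -> 64 -> 1 ----

cnn_init <- function() {
  list(W1 = he_init(6, 32), b1 = numeric(32),
       W2 = he_init(96, 64), b2 = numeric(64),
       W3 = he_init(64, 64), b3 = numeric(64),
       W4 = he_init(64, 1), b4 = numeric(1))
}

# im2col for the first conv: rows (position-major) = n*11, cols = 2ch x 3k
cnn_col1 <- function(X) {
  n <- nrow(X)
  xc <- X[, seq(1, 26, 2), drop = FALSE]
  yc <- X[, seq(2, 26, 2), drop = FALSE]
  col1 <- matrix(0, n * 11, 6)
  for (p in 1:11) {
    rows <- (p - 1) * n + seq_len(n)
    col1[rows, 1:3] <- xc[, p:(p + 2)]
    col1[rows, 4:6] <- yc[, p:(p + 2)]
  }
  col1
}

cnn_forward <- function(p, X, dropout = 0, train = FALSE) {
  n <- nrow(X)
  col1 <- cnn_col1(X)
  Z1 <- addb(col1 %*% p$W1, p$b1)                   # (n*11) x 32
  m1 <- if (train) drop_mask(nrow(Z1), 32, dropout) else NULL
  A1 <- apply_mask(relu(Z1), m1)
  col2 <- matrix(0, n * 9, 96)
  for (pp in 1:9) for (k in 0:2) {
    col2[(pp - 1) * n + seq_len(n), k * 32 + 1:32] <-
      A1[(pp + k - 1) * n + seq_len(n), ]
  }
  Z2 <- addb(col2 %*% p$W2, p$b2)                   # (n*9) x 64
  m2 <- if (train) drop_mask(nrow(Z2), 64, dropout) else NULL
  A2 <- apply_mask(relu(Z2), m2)
  pool <- matrix(0, n, 64)                          # global average pool
  for (pp in 1:9) pool <- pool + A2[(pp - 1) * n + seq_len(n), ]
  pool <- pool / 9
  Z3 <- addb(pool %*% p$W3, p$b3)
  m3 <- if (train) drop_mask(n, 64, dropout) else NULL
  A3 <- apply_mask(relu(Z3), m3)
  out <- addb(A3 %*% p$W4, p$b4)
  list(pred = drop(out),
       cache = list(n = n, col1 = col1, Z1 = Z1, A1 = A1, col2 = col2,
                    Z2 = Z2, A2 = A2, pool = pool, Z3 = Z3, A3 = A3,
                    m1 = m1, m2 = m2, m3 = m3))
}

cnn_backward <- function(p, cache, dout) {
  n <- cache$n
  dout <- matrix(dout, ncol = 1)
  dW4 <- crossprod(cache$A3, dout); db4 <- colSums(dout)
  dA3 <- apply_mask(dout %*% t(p$W4), cache$m3)
  dZ3 <- dA3 * (cache$Z3 > 0)
  dW3 <- crossprod(cache$pool, dZ3); db3 <- colSums(dZ3)
  dpool <- dZ3 %*% t(p$W3)
  dA2 <- matrix(0, n * 9, 64)
  for (pp in 1:9) dA2[(pp - 1) * n + seq_len(n), ] <- dpool / 9
  dA2 <- apply_mask(dA2, cache$m2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$col2, dZ2); db2 <- colSums(dZ2)
  dcol2 <- dZ2 %*% t(p$W2)
  dA1 <- matrix(0, n * 11, 32)
  for (pp in 1:9) for (k in 0:2) {
    dA1[(pp + k - 1) * n + seq_len(n), ] <-
      dA1[(pp + k - 1) * n + seq_len(n), ] +
      dcol2[(pp - 1) * n + seq_len(n), k * 32 + 1:32]
  }
  dA1 <- apply_mask(dA1, cache$m1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$col1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       W4 = dW4, b4 = db4)
}

## ---- GCN: 13 nodes x 2 features, fixed skeleton graph with self-loops and
## symmetric normalized adjacency; 2 conv layers hidden 64; head
## 832 -> 256 -> 128 -> 64 -> 1 ----

#' Skeleton graph edges used by the GCN
#'
#' Anatomical chains on the 13-keypoint skeleton: head-shoulders, the two
#' arm chains (shoulder-elbow-wrist), shoulder girdle, shoulders-hips,
#' pelvis (hip-hip), and the two leg chains (hip-knee-ankle). Self-loops are
#' added when the adjacency is normalized.
#'
#' @return two-column character matrix of undirected edges.
#' @export
skeleton_graph_edges <- function() {
  rbind(
    c("head", "shoulder_l"), c("head", "shoulder_r"),
    c("shoulder_l", "shoulder_r"),
    c("shoulder_l", "elbow_l"), c("elbow_l", "wrist_l"),
    c("shoulder_r", "elbow_r"), c("elbow_r", "wrist_r"),
    c("shoulder_l", "hip_l"), c("shoulder_r", "hip_r"),
    c("hip_l", "hip_r"),
    c("hip_l", "knee_l"), c("knee_l", "ankle_l"),
    c("hip_r", "knee_r"), c("knee_r", "ankle_r")
  )
}

# D^{-1/2} (A + I) D^{-1/2} over the 13 keypoints
gcn_adjacency <- function(edges = skeleton_graph_edges()) {
  kp <- humanoid_model()$keypoint_names
  A <- matrix(0, 13, 13, dimnames = list(kp, kp))
  for (e in seq_len(nrow(edges))) {
    i <- match(edges[e, 1], kp); j <- match(edges[e, 2], kp)
    A[i, j] <- 1; A[j, i] <- 1
  }
  A <- A + diag(13)
  d <- 1 / sqrt(rowSums(A))
  A * outer(d, d)
}

gcn_init <- function() {
  Ahat <- gcn_adjacency()
  list(params = list(
         W1 = he_init(2, 64), b1 = numeric(64),
         W2 = he_init(64, 64), b2 = numeric(64),
         H1 = he_init(832, 256), c1 = numeric(256),
         H2 = he_init(256, 128), c2 = numeric(128),
         H3 = he_init(128, 64), c3 = numeric(64),
         H4 = he_init(64, 1), c4 = numeric(1)),
       K2 = kronecker(Ahat, diag(2)),
       K64 = kronecker(Ahat, diag(64)))
}

# node-major block matrix n x (13 f) <-> long (n*13) x f
gcn_to_long <- function(H, f) {
  n <- nrow(H)
  matrix(aperm(array(H, c(n, f, 13)), c(1, 3, 2)), n * 13, f)
}
gcn_to_blk <- function(L, f) {
  n <- nrow(L) / 13
  matrix(aperm(array(L, c(n, 13, f)), c(1, 3, 2)), n, 13 * f)
}

gcn_forward <- function(p, X, aux, dropout = 0, train = FALSE) {
  n <- nrow(X)
  Agg1 <- X %*% aux$K2
  L1 <- gcn_to_long(Agg1, 2)
  Z1 <- addb(L1 %*% p$W1, p$b1)                 # (n*13) x 64
  m1 <- if (train) drop_mask(nrow(Z1), 64, dropout) else NULL
  A1 <- apply_mask(relu(Z1), m1)
  B1 <- gcn_to_blk(A1, 64)                      # n x 832
  Agg2 <- B1 %*% aux$K64
  L2 <- gcn_to_long(Agg2, 64)
  Z2 <- addb(L2 %*% p$W2, p$b2)
  m2 <- if (train) drop_mask(nrow(Z2), 64, dropout) else NULL
  A2 <- apply_mask(relu(Z2), m2)
  F0 <- gcn_to_blk(A2, 64)                      # n x 832 flattened
  ZH1 <- addb(F0 %*% p$H1, p$c1)
  mh1 <- if (train) drop_mask(n, 256, dropout) else NULL
  AH1 <- apply_mask(relu(ZH1), mh1)
  ZH2 <- addb(AH1 %*% p$H2, p$c2)
  mh2 <- if (train) drop_mask(n, 128, dropout) else NULL
  AH2 <- apply_mask(relu(ZH2), mh2)
  ZH3 <- addb(AH2 %*% p$H3, p$c3)
  mh3 <- if (train) drop_mask(n, 64, dropout) else NULL
  AH3 <- apply_mask(relu(ZH3), mh3)
  out <- addb(AH3 %*% p$H4, p$c4)
  list(pred = drop(out),
       cache = list(X = X, L1 = L1, Z1 = Z1, L2 = L2, Z2 = Z2, F0 = F0,
                    ZH1 = ZH1, AH1 = AH1, ZH2 = ZH2, AH2 = AH2,
                    ZH3 = ZH3, AH3 = AH3,
                    m1 = m1, m2 = m2, mh1 = mh1, mh2 = mh2, mh3 = mh3))
}

gcn_backward <- function(p, cache, dout, aux) {
  dout <- matrix(dout, ncol = 1)
  dH4 <- crossprod(cache$AH3, dout); dc4 <- colSums(dout)
  dAH3 <- apply_mask(dout %*% t(p$H4), cache$mh3)
  dZH3 <- dAH3 * (cache$ZH3 > 0)
  dH3 <- crossprod(cache$AH2, dZH3); dc3 <- colSums(dZH3)
  dAH2 <- apply_mask(dZH3 %*% t(p$H3), cache$mh2)
  dZH2 <- dAH2 * (cache$ZH2 > 0)
  dH2 <- crossprod(cache$AH1, dZH2); dc2 <- colSums(dZH2)
  dAH1 <- apply_mask(dZH2 %*% t(p$H2), cache$mh1)
  dZH1 <- dAH1 * (cache$ZH1 > 0)
  dH1 <- crossprod(cache$F0, dZH1); dc1 <- colSums(dZH1)
  dF0 <- dZH1 %*% t(p$H1)
  dA2 <- apply_mask(gcn_to_long(dF0, 64), cache$m2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$L2, dZ2); db2 <- colSums(dZ2)
  dAgg2 <- gcn_to_blk(dZ2 %*% t(p$W2), 64)
  dB1 <- dAgg2 %*% t(aux$K64)
  dA1 <- apply_mask(gcn_to_long(dB1, 64), cache$m1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$L1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       H1 = dH1, c1 = dc1, H2 = dH2, c2 = dc2,
       H3 = dH3, c3 = dc3, H4 = dH4, c4 = dc4)
}

## ---- LSTM: input (5, 26), one layer hidden 64, head 64 -> 1 on the last
## hidden state, dropout on the last hidden state ----

lstm_init <- function(d_in = 26, d_h = 64) {
  s <- 1 / sqrt(d_h)
  b <- numeric(4 * d_h)
  b[(d_h + 1):(2 * d_h)] <- 1  # forget-gate bias init
  list(Wx = unif_init(d_in, 4 * d_h, s), Wh = unif_init(d_h, 4 * d_h, s),
       b = b, Wy = unif_init(d_h, 1, s), by = numeric(1))
}

lstm_forward <- function(p, X, dropout = 0, train = FALSE,
                         n_steps = 5, d_in = 26) {
  n <- nrow(X); d_h <- nrow(p$Wh)
  h <- matrix(0, n, d_h); cc <- matrix(0, n, d_h)
  caches <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    Xt <- X[, (t - 1) * d_in + seq_len(d_in), drop = FALSE]
    G <- addb(Xt %*% p$Wx + h %*% p$Wh, p$b)
    ig <- sigm(G[, 1:d_h, drop = FALSE])
    fg <- sigm(G[, d_h + 1:d_h, drop = FALSE])
    gg <- tanh(G[, 2 * d_h + 1:d_h, drop = FALSE])
    og <- sigm(G[, 3 * d_h + 1:d_h, drop = FALSE])
    c_new <- fg * cc + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    caches[[t]] <- list(Xt = Xt, hprev = h, cprev = cc, i = ig, f = fg,
                        g = gg, o = og, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
  }
  mk <- if (train) drop_mask(n, d_h, dropout) else NULL
  hd <- apply_mask(h, mk)
  out <- addb(hd %*% p$Wy, p$by)
  list(pred = drop(out), cache = list(caches = caches, hd = hd, mk = mk,
                                      n_steps = n_steps, d_h = d_h))
}

lstm_backward <- function(p, cache, dout) {
  d_h <- cache$d_h
  dout <- matrix(dout, ncol = 1)
  dWy <- crossprod(cache$hd, dout); dby <- colSums(dout)
  dh <- apply_mask(dout %*% t(p$Wy), cache$mk)
  dc <- matrix(0, nrow(dh), d_h)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  for (t in rev(seq_len(cache$n_steps))) {
    cc <- cache$caches[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$cprev
    dc_prev <- dc * cc$f
    G <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
               dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$Xt, G)
    dWh <- dWh + crossprod(cc$hprev, G)
    db <- db + colSums(G)
    dh <- G %*% t(p$Wh)
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, Wy = dWy, by = dby)
}

## ---- shared Adam trainer ----

adam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Generic mini-batch MSE trainer with min-validation-loss checkpointing.
# fwd(params, X, train) -> list(pred, cache); bwd(params, cache, dout).
train_loop <- function(params, fwd, bwd, X, y, Xval, yval, config) {
  st <- adam_new(params)
  n <- nrow(X)
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    tot <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      f <- fwd(params, X[idx, , drop = FALSE], train = TRUE)
      resid <- f$pred - y[idx]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("NaN/Inf training loss at epoch %d batch %d", epoch, b))
      }
      tot <- tot + loss * length(idx)
      grads <- bwd(params, f$cache, 2 * resid / length(idx))
      up <- adam_update(params, grads, st, config$learning_rate)
      params <- up$params; st <- up$state
    }
    val_pred <- fwd(params, Xval, train = FALSE)$pred
    val_loss <- mean((val_pred - yval)^2)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tot / n, val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = params, epoch = epoch)
    }
  }
  list(params = best$params, history = history,
       selected_epoch = best$epoch, best_val = best$val)
}
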