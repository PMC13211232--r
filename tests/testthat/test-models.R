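# shared finite-difference gradient checker
check_gradients <- function(family, n = 4, n_checks = 6, tol = 1e-5) {
  d <- if (family == "lstm") 130 else 26
  m <- build_model(family, seed = 7)
  set.seed(300 + match(family, c("mlp", "cnn", "gcn", "lstm")))
  X <- matrix(rnorm(n * d), n, d)
  y <- runif(n)
  fb <- bedfall:::model_fwd_bwd(m, train_config(dropout = 0))
  f <- fb$fwd(m$params, X, train = FALSE)
  g <- fb$bwd(m$params, f$cache, 2 * (f$pred - y) / n)
  for (chk in seq_len(n_checks)) {
    pn <- sample(names(m$params), 1)
    i <- sample(length(m$params[[pn]]), 1)
    eps <- 1e-6
    p2 <- m$params
    p2[[pn]][i] <- p2[[pn]][i] + eps
    l1 <- mean((fb$fwd(p2, X, train = FALSE)$pred - y)^2)
    p2[[pn]][i] <- p2[[pn]][i] - 2 * eps
    l0 <- mean((fb$fwd(p2, X, train = FALSE)$pred - y)^2)
    numeric_grad <- (l1 - l0) / (2 * eps)
    expect_equal(g[[pn]][i], numeric_grad, tolerance = tol,
                 label = sprintf("%s gradient of %s[%d]", family, pn, i))
  }
}

test_that("architectures match their printed layer sizes", {
  expect_equal(count_params(build_model("mlp")), 39937)
  gcn <- build_model("gcn")
  expect_equal(dim(gcn$params$H1), c(832, 256))   # head input = 13 x 64
  cnn <- build_model("cnn")
  expect_equal(dim(cnn$params$W1), c(6, 32))      # 2 channels x kernel 3
  expect_equal(dim(cnn$params$W2), c(96, 64))     # 32 channels x kernel 3
  # 13 positions - 2 - 2 = 9 survive two valid length-3 convolutions
  f <- bedfall:::cnn_forward(cnn$params, matrix(rnorm(3 * 26), 3, 26))
  expect_equal(nrow(f$cache$Z2), 3 * 9)
  expect_equal(dim(f$cache$pool), c(3, 64))
  lstm <- build_model("lstm")
  expect_equal(dim(lstm$params$Wx), c(26, 256))
  expect_error(build_model("transformer"))
})

test_that("analytic gradients agree with finite differences", {
  for (family in c("mlp", "cnn", "gcn", "lstm")) check_gradients(family)
})

test_that("the GCN adjacency is the normalized skeleton graph with self-loops", {
  A <- bedfall:::gcn_adjacency()
  expect_equal(dim(A), c(13, 13))
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) > 0))                       # self-loops
  expect_equal(A["head", "shoulder_l"] > 0, TRUE)
  expect_equal(A["head", "ankle_r"], 0)               # no spurious edges
  # symmetric normalization: rebuild from the raw adjacency
  raw <- (A > 0) * 1
  d <- rowSums(raw)
  expect_equal(A, raw * outer(1 / sqrt(d), 1 / sqrt(d)), tolerance = 1e-12)
})

test_that("training recovers a constant target and a linear map", {
  # Adam moves parameters by about the learning rate per update, so these
  # recovery properties need enough updates: sizes/batches chosen to give
  # a few thousand steps within the 50-epoch budget.
  set.seed(201)
  X <- matrix(runif(8000 * 26, -1, 1), 8000, 26)
  tr <- 1:7200; va <- 7201:8000
  y_const <- rep(0.5, 8000)
  m <- train_model(build_model("mlp", 41), X[tr, ], y_const[tr],
                   X[va, ], y_const[va], train_config(batch_size = 128))
  expect_lt(sqrt(mse(predict(m, X[va, ]), y_const[va])), 0.01)

  w_true <- rnorm(26, 0, 0.2)
  y_lin <- drop(X[1:6000, ] %*% w_true) + 0.3
  m2 <- train_model(build_model("mlp", 41), X[1:5400, ], y_lin[1:5400],
                    X[5401:6000, ], y_lin[5401:6000],
                    train_config(batch_size = 64))
  expect_lt(mse(predict(m2, X[5401:6000, ]), y_lin[5401:6000]), 1e-3)
})

test_that("training is seed-deterministic and records its history", {
  set.seed(202)
  X <- matrix(runif(300 * 26, -1, 1), 300, 26)
  y <- drop(abs(X[, 1]) + 0.1 * X[, 2])
  cfg <- train_config(max_epochs = 5)
  m1 <- train_model(build_model("mlp", 41), X[1:250, ], y[1:250],
                    X[251:300, ], y[251:300], cfg)
  m2 <- train_model(build_model("mlp", 41), X[1:250, ], y[1:250],
                    X[251:300, ], y[251:300], cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_equal(nrow(m1$history), 5)
  expect_equal(m1$selected_epoch,
               m1$history$epoch[which.min(m1$history$val_loss)])
  # NaN losses abort with diagnostics
  Xbad <- X; Xbad[1, 1] <- Inf
  expect_error(train_model(build_model("mlp", 41), Xbad[1:250, ], y[1:250],
                           X[251:300, ], y[251:300], cfg), "loss")
})

test_that("inference is deterministic and batch-invariant", {
  set.seed(203)
  X <- matrix(rnorm(20 * 26), 20, 26)
  for (family in c("mlp", "cnn", "gcn")) {
    m <- build_model(family, seed = 9)
    s1 <- predict(m, X)
    s2 <- predict(m, X)
    expect_identical(s1, s2)
    per_row <- vapply(1:20, function(i) predict(m, X[i, ]), numeric(1))
    expect_equal(per_row, s1, tolerance = 1e-12)
  }
  expect_error(predict(build_model("mlp", 9), matrix(0, 2, 25)), "columns")
})

test_that("the random forest behaves like a seeded bounded regressor", {
  set.seed(204)
  X <- matrix(runif(400 * 26, -1, 1), 400, 26)
  y <- drop(abs(X %*% rnorm(26, 0, 0.3))) + rnorm(400, 0, 0.3)
  rf <- train_rf(X[1:300, ], y[1:300], seed = 41)
  tr_mse <- mse(predict(rf, X[1:300, ]), y[1:300])
  te_mse <- mse(predict(rf, X[301:400, ]), y[301:400])
  expect_lt(tr_mse, te_mse)                       # forests overfit training
  preds <- predict(rf, X[301:400, ])
  expect_true(all(preds >= min(y[1:300]) & preds <= max(y[1:300])))
  rf2 <- train_rf(X[1:300, ], y[1:300], seed = 41)
  expect_identical(predict(rf2, X[301:400, ]), preds)
})

test_that("LSTM sequences are built on the 30 fps grid from episode frames", {
  b <- bed_bounds(test_world())
  set.seed(205)
  frames <- matrix(runif(5 * 26, -1, 0.45), 5, 26)
  seqv <- build_lstm_sequence(frames, b)
  expect_length(seqv, 130)
  # frame-major layout: the k-th block is the normalized k-th frame
  for (k in 1:5) {
    expect_equal(seqv[(k - 1) * 26 + 1:26],
                 bedfall:::frame_to_features(frames[k, ], b),
                 tolerance = 1e-12)
  }
  # the snapshot grid lands on steps ceiling(k / (fps dt))
  w <- test_world()
  st <- settled_supine_state(w)
  oc <- rollout_and_detect(w, st, episode_config())
  expect_equal(nrow(oc$frames), 5)
  expect_false(anyNA(oc$frames))
  dt <- w$config$sim_timestep
  expect_identical(as.integer(ceiling((0:4) / (30 * dt))),
                   c(0L, 7L, 14L, 20L, 27L))
  # a constant sequence predicts the same as any other constant repeat
  m <- build_model("lstm", seed = 5)
  one <- runif(26)
  s1 <- predict(m, rep(one, 5))
  s2 <- predict(m, rep(one, 5))
  expect_identical(s1, s2)
})
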