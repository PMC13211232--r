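# Independent brute-force oracles used to check the evaluator, plus small
# shared fixtures. The oracles deliberately avoid the package's own
# implementations.

# AUROC by exhaustive comparison of every positive-negative pair
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# AUPRC by step-wise integration over thresholds at each unique score
auprc_brute <- function(scores, labels) {
  np <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

f1_at <- function(scores, labels, tau) {
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# best achievable F1 over an exhaustive threshold sweep
best_f1_brute <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u, Inf)
  max(vapply(cand, function(t) f1_at(scores, labels, t), numeric(1)))
}

mse_brute <- function(pred, y) {
  acc <- 0
  for (i in seq_along(pred)) acc <- acc + (pred[i] - y[i])^2
  acc / length(pred)
}

# one shared default world for physics tests (construction is cheap but
# reusing one object keeps intent clear)
test_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- build_world(world_config())
    w
  }
})

# a settled supine-at-centre episode start state
settled_supine_state <- function(world = test_world()) {
  tgt <- structure(list(planar_xy = c(0, 0), root_quat = c(1, 0, 0, 0),
                        joints = reset_joints(world$model), mode = "supine"),
                   class = "initial_configuration")
  posed <- pre_pose(world, tgt, 1, 2)
  dr <- drop_to_contact(world, posed, 2)
  stopifnot(dr$status == "ok")
  dr$state
}
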