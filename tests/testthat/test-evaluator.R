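test_that("AUROC matches its definition on canonical cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "one class")
})

test_that("AUPRC collapses to prevalence under constant scores", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "no positives")
})

test_that("ranking metrics agree with brute-force oracles on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_brute(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auprc(scores, labels), auprc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("threshold calibration attains the brute-force F1 optimum", {
  # perfectly separated: the gap midpoint
  expect_equal(calibrate_threshold(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)),
               0.55)
  # all scores equal: predict-all-positive (tau = -Inf) maximizes F1
  expect_identical(calibrate_threshold(rep(0.4, 6), c(1, 1, 1, 1, 0, 0)),
                   -Inf)
  set.seed(102)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    tau <- calibrate_threshold(scores, labels)
    expect_equal(f1_at(scores, labels, tau), best_f1_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("thresholded metrics follow the contingency definitions", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3, 0.2, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- thresholded_metrics(scores, labels, 0.5)
  expect_equal(unname(m), c(0.8, 0.75, 0.75, 0.75))

  perfect <- thresholded_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  none <- thresholded_metrics(c(0.1, 0.2), c(1, 0), 0.9)
  expect_equal(unname(none[c("precision", "recall", "f1")]), c(0, 0, 0))
})

test_that("MSE matches an independent accumulation oracle", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 1), c(1, 0)), 1)
  expect_error(mse(numeric(0), numeric(0)), "empty")
  set.seed(103)
  for (i in 1:20) {
    p <- rnorm(20); y <- rnorm(20)
    expect_equal(mse(p, y), mse_brute(p, y), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant to monotone transforms and flips with labels", {
  set.seed(104)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(3 * scores) + 2, labels), a, tolerance = 1e-12)
  expect_equal(auroc(scores, 1 - labels), 1 - a, tolerance = 1e-12)
})

test_that("a random scorer earns AUPRC near the 0.5 prevalence", {
  set.seed(105)
  vals <- replicate(40, auprc(runif(500), rbinom(500, 1, 0.5)))
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("per-posture reports reuse the global threshold and decompose the MSE", {
  set.seed(106)
  n <- 400
  modes <- rep(posture_modes(), each = n / 4)
  y <- ifelse(rbinom(n, 1, 0.5) == 1, runif(n, 0.41, 1), 0)
  c_lab <- as.integer(y > 0)
  scores <- pmin(pmax(y + rnorm(n, 0, 0.2), -0.2), 1.2)
  tau <- calibrate_threshold(scores, c_lab)
  rep <- per_posture_report(scores, c_lab, y, modes, tau)
  expect_identical(rep$subgroup, c("overall", posture_modes()))
  expect_true(all(rep$n_samples[-1] == n / 4))
  expect_true(all(rep$threshold == tau))
  pooled <- sum(rep$mse[-1] * rep$n_samples[-1]) / n
  expect_equal(rep$mse[1], pooled, tolerance = 1e-12)

  # identical score/label multisets per mode give identical subgroup rows
  scores4 <- rep(scores[1:25], 4)
  y4 <- rep(y[1:25], 4); c4 <- as.integer(y4 > 0)
  modes4 <- rep(posture_modes(), each = 25)
  r4 <- per_posture_report(scores4, c4, y4, modes4, tau)
  sub <- r4[r4$subgroup != "overall",
            setdiff(names(r4), "subgroup")]
  expect_true(all(vapply(2:4, function(i) {
    isTRUE(all.equal(sub[1, ], sub[i, ], check.attributes = FALSE))
  }, logical(1))))

  # a single-class subgroup reports NA ranking metrics, others intact
  modes_bad <- modes
  c_bad <- c_lab
  c_bad[modes == "supine"] <- 1L
  y_bad <- y; y_bad[modes == "supine" & y == 0] <- 0.5
  r_bad <- per_posture_report(scores, c_bad, y_bad, modes_bad, tau)
  expect_true(is.na(r_bad$auroc[r_bad$subgroup == "supine"]))
  expect_false(anyNA(r_bad$auroc[r_bad$subgroup %in%
                                   c("prone", "left_lateral")]))
})

test_that("multi-seed aggregation reports mean and sd per subgroup", {
  set.seed(107)
  reps <- lapply(1:3, function(s) {
    data.frame(subgroup = c("overall", "supine"), n_samples = c(100, 25),
               auroc = runif(2), auprc = runif(2), accuracy = runif(2),
               precision = runif(2), recall = runif(2), f1 = runif(2),
               mse = runif(2))
  })
  agg <- aggregate_reports(reps)
  expect_equal(agg$n_seeds, c(3, 3))
  got <- agg$auroc_mean[1]
  expect_equal(got, mean(sapply(reps, function(r) r$auroc[1])))
  expect_equal(agg$f1_sd[2], sd(sapply(reps, function(r) r$f1[2])))
})
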