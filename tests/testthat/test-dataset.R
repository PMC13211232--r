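small_balanced <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- build_balanced_dataset(test_world(), n_total = 60, seed = 11)
    }
    ds
  }
})

test_that("class balancing hits exact quotas with consistent labels", {
  ds <- small_balanced()
  expect_equal(nrow(ds), 60)
  expect_equal(sum(ds$c == 1), 30)
  expect_equal(sum(ds$c == 0), 30)
  expect_true(all((ds$c == 1) == (ds$y > 0)))
  lc <- attr(ds, "label_config")
  fall_y <- ds$y[ds$c == 1]
  expect_true(all(fall_y >= min_fall_label(lc) & fall_y <= 1))
  st <- attr(ds, "stats")
  expect_gte(st$attempts, 60)
  expect_true(all(names(st$rejections) %in%
                    c("floor_before_bed", "timeout", "unstable")))

  odd <- build_balanced_dataset(test_world(), n_total = 11, seed = 12)
  expect_equal(sum(odd$c == 1), 6)  # ceiling(11/2) falls
  expect_equal(sum(odd$c == 0), 5)
})

test_that("pose-balanced test sets have exact per-mode quotas", {
  ds <- build_pose_balanced_test_set(test_world(), n_test = 8, seed = 13)
  expect_equal(unname(table(factor(ds$mode, posture_modes()))),
               rep(2L, 4), ignore_attr = TRUE)
  expect_error(build_pose_balanced_test_set(test_world(), n_test = 10,
                                            seed = 13), "divisible by 4")
  expect_error(build_pose_balanced_test_set(
    test_world(), sampler_config("fully_random"), n_test = 8, seed = 13),
    "pose-stratified")
})

test_that("train/validation splitting is disjoint, exhaustive and seeded", {
  ds <- small_balanced()
  sp <- split_train_val(ds, 0.9, seed = 3)
  expect_equal(nrow(sp$train), 54)
  expect_equal(nrow(sp$val), 6)
  merged <- rbind(sp$train, sp$val)
  expect_equal(nrow(merged), nrow(ds))
  expect_setequal(merged$episode_seed, ds$episode_seed)
  expect_length(intersect(sp$train$episode_seed, sp$val$episode_seed), 0)
  sp2 <- split_train_val(ds, 0.9, seed = 3)
  expect_identical(sp$train$episode_seed, sp2$train$episode_seed)
})

test_that("CSV persistence round-trips losslessly with metadata", {
  ds <- small_balanced()
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_identical(back$c, ds$c)
  expect_identical(back$mode, ds$mode)
  expect_identical(back$y, ds$y)                 # full float precision
  expect_identical(as.matrix(back[, bedfall:::u_cols()]),
                   as.matrix(ds[, bedfall:::u_cols()]))
  lc <- attr(back, "label_config")
  expect_equal(lc$gamma, attr(ds, "label_config")$gamma)
  expect_equal(attr(back, "bounds"), attr(ds, "bounds"))

  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), nrow(ds) + 1)  # header + rows
  expect_gte(sum(startsWith(lines, "#")), 1)
})

test_that("malformed CSV files are rejected with the offending line", {
  ds <- small_balanced()
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  lines <- readLines(path)

  # wrong schema: drop a feature column from the header and every row
  mangled <- sub(",u_25", "", lines)
  path2 <- tempfile(fileext = ".csv")
  writeLines(mangled, path2)
  expect_error(read_dataset_csv(path2), "parse error")

  # one truncated data line
  bad <- lines
  bad[length(bad)] <- sub(",[^,]*$", "", bad[length(bad)])
  path3 <- tempfile(fileext = ".csv")
  writeLines(bad, path3)
  expect_error(read_dataset_csv(path3), "line")
})

test_that("stratified balanced sets keep roughly uniform mode coverage", {
  ds <- build_balanced_dataset(test_world(), n_total = 400, seed = 14)
  counts <- table(factor(ds$mode, posture_modes()))
  half <- stats::qnorm(0.995) * sqrt(400 * 0.25 * 0.75)  # 99% interval
  expect_true(all(abs(counts - 100) < half + 1))
})

test_that("dataset generation is reproducible from its seed", {
  a <- build_balanced_dataset(test_world(), n_total = 20, seed = 15)
  b <- build_balanced_dataset(test_world(), n_total = 20, seed = 15)
  expect_identical(a$y, b$y)
  expect_identical(a$episode_seed, b$episode_seed)
  expect_identical(as.matrix(a[, bedfall:::u_cols()]),
                   as.matrix(b[, bedfall:::u_cols()]))
})
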