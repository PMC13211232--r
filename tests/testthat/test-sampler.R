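test_that("planar positions are uniform on the margin-shrunk footprint", {
  b <- bed_bounds(test_world())
  set.seed(71)
  draws <- t(replicate(10000, sample_planar_position(b, 0.1)))
  expect_true(all(draws[, 1] >= b$x_min + 0.1 & draws[, 1] <= b$x_max - 0.1))
  expect_true(all(draws[, 2] >= b$y_min + 0.1 & draws[, 2] <= b$y_max - 0.1))
  ksx <- stats::ks.test(draws[, 1], "punif", b$x_min + 0.1, b$x_max - 0.1)
  ksy <- stats::ks.test(draws[, 2], "punif", b$y_min + 0.1, b$y_max - 0.1)
  expect_gt(ksx$p.value, 0.01)
  expect_gt(ksy$p.value, 0.01)

  expect_error(sample_planar_position(b, 0.5), "empty feasible region")
})

test_that("zero-sigma stratified orientation reproduces the preset exactly", {
  cfg <- sampler_config("pose_stratified", sigma_deg = 0)
  for (m in posture_modes()) {
    q <- sample_root_orientation(cfg, m)
    preset <- posture_presets()[[m]]
    expect_equal(q, bedfall:::quat_from_euler(preset[1], preset[2], preset[3]),
                 tolerance = 1e-12)
  }
})

test_that("sampled orientations are unit quaternions with the stated spread", {
  set.seed(72)
  cfg <- sampler_config("pose_stratified", sigma_deg = 15)
  qs <- replicate(1000, sample_root_orientation(cfg, "supine"))
  expect_true(all(abs(colSums(qs^2) - 1) < 1e-9))

  # recovered per-axis Euler sd ~ 15 degrees within 5% (supine preset = 0)
  eul <- t(replicate(10000, bedfall:::quat_to_euler(
    sample_root_orientation(cfg, "supine"))))
  sds <- apply(eul, 2, sd) * 180 / pi
  expect_true(all(abs(sds - 15) / 15 < 0.05))
})

test_that("orientation sampling enforces the strategy/mode contract", {
  expect_error(sample_root_orientation(sampler_config("pose_stratified")),
               "requires a posture mode")
  expect_error(
    sample_root_orientation(sampler_config("fully_random"), "supine"),
    "no posture mode")
  expect_error(sample_root_orientation(
    sampler_config("pose_stratified"), "sideways"), "unknown posture mode")
})

test_that("joint sampling respects limits, defaults and ball-joint uniformity", {
  set.seed(73)
  jd <- data.frame(name = c("a", "b", "c"),
                   kind = c("hinge", "hinge", "ball"),
                   lower = c(-1, NA, NA), upper = c(1, NA, NA))
  cfg <- sampler_config("fully_random", joint_range_default = pi / 4)
  draws <- replicate(2000, sample_joint_angles(jd, cfg), simplify = FALSE)
  a <- vapply(draws, `[[`, numeric(1), "a")
  b <- vapply(draws, `[[`, numeric(1), "b")
  expect_true(all(a >= -1 & a <= 1))
  expect_true(all(abs(b) <= pi / 4))

  # degenerate default range pins unlimited hinges at zero
  cfg0 <- sampler_config("fully_random", joint_range_default = 0)
  expect_identical(sample_joint_angles(jd, cfg0)$b, 0)

  # ball joints: mean dot-product with a fixed unit quaternion ~ 0
  qs <- vapply(draws, `[[`, numeric(4), "c")
  expect_true(all(abs(colSums(qs^2) - 1) < 1e-9))
  ref <- c(0.5, 0.5, 0.5, 0.5)
  expect_lt(abs(mean(colSums(qs * ref))), 4 / sqrt(2000))
})

test_that("full configuration sampling balances modes and is reproducible", {
  w <- test_world()
  jd <- w$model$joint_descriptors
  cfg <- sampler_config("pose_stratified")
  set.seed(74)
  modes <- replicate(20000, sample_initial_configuration(
    cfg, bed_bounds(w), jd)$mode)
  counts <- table(factor(modes, levels = posture_modes()))
  # 99% binomial interval around 20000/4
  half <- stats::qnorm(0.995) * sqrt(20000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 5000) < half + 1))

  expect_true(is.na(sample_initial_configuration(
    sampler_config("fully_random"), bed_bounds(w), jd)$mode))

  set.seed(75)
  s1 <- replicate(5, sample_initial_configuration(cfg, bed_bounds(w), jd),
                  simplify = FALSE)
  set.seed(75)
  s2 <- replicate(5, sample_initial_configuration(cfg, bed_bounds(w), jd),
                  simplify = FALSE)
  expect_identical(s1, s2)
})

test_that("sampled configurations satisfy their invariants", {
  w <- test_world()
  jd <- w$model$joint_descriptors
  b <- bed_bounds(w)
  cfg <- sampler_config("pose_stratified")
  set.seed(76)
  for (i in 1:200) {
    ic <- sample_initial_configuration(cfg, b, jd)
    expect_true(ic$planar_xy[1] >= b$x_min + 0.1 &&
                ic$planar_xy[1] <= b$x_max - 0.1)
    expect_lt(abs(sum(ic$root_quat^2) - 1), 1e-9)
    expect_true(ic$mode %in% posture_modes())
    hinges <- jd$name[jd$kind == "hinge"]
    for (h in hinges) {
      expect_true(ic$joints[[h]] >= jd$lower[jd$name == h] &&
                  ic$joints[[h]] <= jd$upper[jd$name == h])
    }
  }
})
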