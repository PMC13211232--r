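make_target <- function(world, planar = c(0, 0), quat = c(1, 0, 0, 0)) {
  structure(list(planar_xy = planar, root_quat = quat,
                 joints = reset_joints(world$model), mode = "supine"),
            class = "initial_configuration")
}

test_that("pre-pose ends at the target configuration at drop height with zero velocities", {
  w <- test_world()
  set.seed(81)
  tgt <- sample_initial_configuration(
    sampler_config("pose_stratified"), bed_bounds(w),
    w$model$joint_descriptors)
  st <- pre_pose(w, tgt, 1, 2)
  expected <- fk_pose(w$model,
                      c(tgt$planar_xy, w$config$bed_top_height + 2),
                      tgt$root_quat, tgt$joints)
  expect_equal(st$pos, expected, tolerance = 1e-12)
  expect_identical(unname(st$vel), matrix(0, w$model$n_points, 3))
  expect_identical(st$t, 0)

  # stepwise interpolation with zeroed velocities reaches the same endpoint
  tr <- pre_pose(w, tgt, 0.1, 2, trace = TRUE)
  expect_equal(tr$state$pos, st$pos, tolerance = 1e-9)
  expect_true(all(vapply(tr$trace,
                         function(s) all(s$vel == 0), logical(1))))

  # root (pelvis midpoint) sits exactly drop_height above the bed top
  root_z <- mean(st$pos[c("hip_l", "hip_r"), 3])
  expect_equal(root_z, w$config$bed_top_height + 2, tolerance = 1e-9)
})

test_that("drop-to-contact freezes at first bed contact with the clock at zero", {
  w <- test_world()
  posed <- pre_pose(w, make_target(w), 1, 2)
  dr <- drop_to_contact(w, posed, 2)
  expect_identical(dr$status, "ok")
  expect_identical(dr$state$t, 0)
  expect_identical(unname(dr$state$vel), matrix(0, w$model$n_points, 3))
  out <- step_world(w, dr$state)
  expect_true("humanoid-bed" %in% out$contacts$kind)
})

test_that("a humanoid beyond the bed footprint is rejected, not labelled", {
  w <- test_world()
  posed <- pre_pose(w, make_target(w, planar = c(5, 0)), 1, 2)
  expect_identical(drop_to_contact(w, posed, 2)$status, "floor_before_bed")
  expect_identical(drop_to_contact(w, posed, 0.05)$status, "timeout")
})

test_that("rollout keeps a centred supine sleeper on the bed and drops an overhanging one", {
  w <- test_world()
  st <- settled_supine_state(w)
  oc <- rollout_and_detect(w, st, episode_config())
  expect_false(oc$fell)
  expect_true(is.na(oc$fall_step))
  expect_false(oc$unstable)

  st_off <- st
  st_off$pos[, 2] <- st_off$pos[, 2] + 0.43  # hang half the body off the edge
  oc2 <- rollout_and_detect(w, st_off, episode_config())
  expect_true(oc2$fell)
  expect_gt(oc2$fall_step, 0)
  expect_lte(oc2$fall_step,
             episode_config()$rollout_window / w$config$sim_timestep)
})

test_that("hand-only floor contact is non-terminal in the contact log", {
  log <- matrix(0L, 100, 2)
  log[10, 2] <- 1L  # hand at step 10
  log[40, 1] <- 1L  # torso at step 40
  expect_identical(adjudicate_contact_log(log), 40L)
  expect_true(is.na(adjudicate_contact_log(matrix(0L, 50, 2))))
  hand_only <- matrix(0L, 50, 2); hand_only[5, 2] <- 1L
  expect_true(is.na(adjudicate_contact_log(hand_only)))
})

test_that("fall step is the first qualifying step of the recorded contact log", {
  w <- test_world()
  set.seed(82)
  checked_fall <- 0
  for (i in 1:40) {
    ep <- run_episode(w)
    if (!ep$accepted) next
    oc <- ep$outcome
    expect_identical(oc$settled_state$t, 0)
    expect_true(all(oc$settled_state$vel == 0))
    expect_true(all(is.finite(oc$final_state$pos)))
    rescanned <- adjudicate_contact_log(oc$contact_log)
    if (oc$fell) {
      checked_fall <- checked_fall + 1
      expect_identical(rescanned, oc$fall_step)
    } else {
      expect_true(is.na(rescanned))
    }
  }
  expect_gt(checked_fall, 0)
})

test_that("episodes are reproducible from their seed and rejections carry reasons", {
  w <- test_world()
  set.seed(83)
  e1 <- run_episode(w)
  set.seed(83)
  e2 <- run_episode(w)
  expect_identical(e1$accepted, e2$accepted)
  expect_identical(e1$config, e2$config)
  if (e1$accepted) {
    expect_identical(e1$outcome$fell, e2$outcome$fell)
    expect_identical(e1$outcome$fall_step, e2$outcome$fall_step)
    expect_identical(e1$outcome$frames, e2$outcome$frames)
  }
  expect_true(e1$reason %in%
                c("ok", "floor_before_bed", "timeout", "unstable"))
})
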