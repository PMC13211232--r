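# One episode: pre-pose interpolation at drop height, drop-to-contact
# initialization with a velocity freeze at first bed contact, a fixed-window
# uncontrolled rollout, and fall/instability adjudication.

#' Episode configuration
#'
#' @param drop_height metres above the bed top at which the humanoid root is
#'   posed before the drop (default 2.0).
#' @param pre_pose_duration seconds over which the reset pose is interpolated
#'   to the target configuration (default 1.0).
#' @param contact_timeout simulated seconds allowed for the drop phase to
#'   reach first bed contact (default 2.0).
#' @param rollout_window rollout length T in seconds (default 3.0); must be a
#'   whole number of simulator steps.
#' @return an `episode_config` list.
#' @export
episode_config <- function(drop_height = 2.0, pre_pose_duration = 1.0,
                           contact_timeout = 2.0, rollout_window = 3.0) {
  vals <- c(drop_height, pre_pose_duration, contact_timeout, rollout_window)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all episode_config values must be positive")
  }
  structure(list(drop_height = drop_height,
                 pre_pose_duration = pre_pose_duration,
                 contact_timeout = contact_timeout,
                 rollout_window = rollout_window),
            class = "episode_config")
}

# minimal-coordinate interpolation between two configurations
interp_config <- function(model, a_pos, a_quat, a_joints,
                          b_pos, b_quat, b_joints, t) {
  pos <- (1 - t) * a_pos + t * b_pos
  quat <- quat_slerp(a_quat, b_quat, t)
  joints <- a_joints
  for (nm in names(joints)) {
    joints[[nm]] <- if (length(a_joints[[nm]]) == 4L) {
      quat_slerp(a_joints[[nm]], b_joints[[nm]], t)
    } else {
      (1 - t) * a_joints[[nm]] + t * b_joints[[nm]]
    }
  }
  list(pos = pos, quat = quat, joints = joints)
}

#' Pose the humanoid at drop height
#'
#' Interpolates the simulator state from the reset pose (identity joints,
#' supine, bed centre) to the target configuration over `duration`, zeroing
#' velocities at every interpolation substep, with the root held
#' `drop_height` above the bed top. Because velocities are zeroed at each
#' substep and no contact is possible at drop height, the final state equals
#' the target configuration exactly; intermediate states are materialised
#' only when `trace = TRUE`.
#'
#' @param world a `bedfall_world`.
#' @param target an `initial_configuration`.
#' @param duration pre-pose duration, seconds.
#' @param drop_height metres above the bed top for the root.
#' @param trace if `TRUE`, also return the interpolated substep states.
#' @return the final `sim_state` (zero velocities, `t = 0`); with
#'   `trace = TRUE`, a list with `state` and `trace` (list of states).
#' @export
pre_pose <- function(world, target, duration = 1.0, drop_height = 2.0,
                     trace = FALSE) {
  model <- world$model
  z_root <- world$config$bed_top_height + drop_height
  b_pos <- c(target$planar_xy, z_root)
  state_at <- function(pos, quat, joints) {
    sim_state(fk_pose(model, pos, quat, joints), t = 0)
  }
  final <- state_at(b_pos, target$root_quat, target$joints)
  if (!trace) return(final)
  a_pos <- c(0, 0, z_root)
  a_quat <- quat_identity()
  a_joints <- reset_joints(model)
  n_sub <- max(1L, round(duration / world$config$sim_timestep))
  states <- lapply(seq_len(n_sub), function(k) {
    cf <- interp_config(model, a_pos, a_quat, a_joints,
                        b_pos, target$root_quat, target$joints, k / n_sub)
    state_at(cf$pos, cf$quat, cf$joints)
  })
  list(state = states[[n_sub]], trace = states)
}

#' Drop the posed humanoid to first bed contact
#'
#' Advances the simulator under gravity until the first humanoid-bed contact,
#' then freezes the dynamics (zero velocities, clock reset to zero) and
#' returns that state as the standardized episode start. The drop phase is
#' excluded from the rollout window. Episodes whose humanoid reaches the
#' floor before the bed, times out, or destabilises are rejected.
#'
#' @param world a `bedfall_world`.
#' @param state the pre-posed `sim_state` (zero velocities).
#' @param timeout maximum simulated seconds for the drop.
#' @return list with `status` (`"ok"`, `"floor_before_bed"`, `"timeout"`,
#'   `"unstable"`), `state` (frozen episode start when `status == "ok"`),
#'   and `steps` taken.
#' @export
drop_to_contact <- function(world, state, timeout = 2.0) {
  stopifnot(inherits(state, "sim_state"))
  max_steps <- max(1L, round(timeout / world$config$sim_timestep))
  res <- eng_drop(state$pos, state$vel, world$engine_params, max_steps)
  status <- switch(as.character(res$result),
                   "0" = "ok", "1" = "floor_before_bed",
                   "2" = "timeout", "3" = "unstable")
  frozen <- NULL
  if (status == "ok") {
    landed <- sim_state(res$P, res$V, t = NA_real_)
    rownames(landed$pos) <- world$model$point_names
    frozen <- freeze(world, landed)
  }
  list(status = status, state = frozen, steps = res$steps)
}

#' First qualifying fall step from a classified contact log
#'
#' Scans a per-step contact log (column 1: any non-hand humanoid-floor
#' contact; column 2: any hand-floor contact) and returns the first step at
#' which a non-hand body part touches the floor. Hand-floor contacts alone
#' are non-terminal.
#'
#' @param log integer matrix with one row per completed step and two columns.
#' @return the 1-based step index of the first qualifying contact, or `NA`.
#' @export
adjudicate_contact_log <- function(log) {
  stopifnot(is.matrix(log), ncol(log) == 2)
  hit <- which(log[, 1] != 0)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Roll out uncontrolled dynamics and detect a fall
#'
#' Steps the world for exactly `rollout_window / sim_timestep` steps or until
#' the first non-hand humanoid-floor contact. Hand-floor contacts are ignored
#' for termination. Skeleton snapshots are recorded on the 30 fps frame grid
#' (steps `ceiling(k / (fps * dt))`) for the first `n_frames` frames;
#' episodes that fall earlier are padded with the last pre-fall frame.
#'
#' @param world a `bedfall_world`.
#' @param start the frozen episode-start `sim_state` (`t = 0`).
#' @param config an [episode_config()].
#' @param fps frame rate of the snapshot grid (default 30).
#' @param n_frames number of snapshot frames retained (default 5).
#' @return an `episode_outcome` list: `fell`, `fall_step` (`NA` when no
#'   fall), `unstable`, `settled_state`, `final_state`, `frames`
#'   (`n_frames` x 26 raw planar coordinates), `contact_log`.
#' @export
rollout_and_detect <- function(world, start, config = episode_config(),
                               fps = 30, n_frames = 5) {
  stopifnot(inherits(start, "sim_state"))
  if (!isTRUE(all.equal(start$t, 0))) {
    stop("rollout must start from a frozen state with t = 0")
  }
  dt <- world$config$sim_timestep
  n_steps_real <- config$rollout_window / dt
  n_steps <- round(n_steps_real)
  if (abs(n_steps_real - n_steps) > 1e-9) {
    stop("rollout_window must be a whole number of simulator steps")
  }
  frame_steps <- as.integer(ceiling((seq_len(n_frames) - 1) / (fps * dt)))
  res <- eng_rollout(start$pos, start$vel, world$engine_params,
                     as.integer(n_steps), frame_steps, 13L)
  frames <- res$frames
  for (f in seq_len(nrow(frames))) { # pad frames past the fall
    if (anyNA(frames[f, ]) && f > 1L) frames[f, ] <- frames[f - 1L, ]
  }
  final_state <- sim_state(res$P, res$V,
                           t = res$steps_run * dt)
  rownames(final_state$pos) <- world$model$point_names
  fell <- res$fall_step > 0
  structure(list(
    fell = fell,
    fall_step = if (fell) as.integer(res$fall_step) else NA_integer_,
    unstable = isTRUE(res$unstable),
    settled_state = start,
    final_state = final_state,
    frames = frames,
    contact_log = res$log[seq_len(res$steps_run), , drop = FALSE]
  ), class = "episode_outcome")
}

#' Run one full episode
#'
#' Composes sampling, pre-pose, drop-to-contact and rollout. Rejections
#' (floor before bed, drop timeout, instability) are reported with a reason,
#' never silently dropped.
#'
#' @param world a `bedfall_world`.
#' @param sampler_cfg a [sampler_config()].
#' @param episode_cfg an [episode_config()].
#' @param force_mode optional posture mode forced on the sampler.
#' @return list with `accepted` (logical), `reason` (`"ok"` or the rejection
#'   reason), `config` (the sampled `initial_configuration`), `start_state`,
#'   `outcome` (an `episode_outcome`, `NULL` on rejection before rollout).
#' @export
run_episode <- function(world, sampler_cfg = sampler_config(),
                        episode_cfg = episode_config(), force_mode = NULL) {
  target <- sample_initial_configuration(
    sampler_cfg, bed_bounds(world), world$model$joint_descriptors,
    force_mode = force_mode)
  posed <- pre_pose(world, target, episode_cfg$pre_pose_duration,
                    episode_cfg$drop_height)
  dropped <- drop_to_contact(world, posed, episode_cfg$contact_timeout)
  if (dropped$status != "ok") {
    return(list(accepted = FALSE, reason = dropped$status, config = target,
                start_state = NULL, outcome = NULL))
  }
  outcome <- rollout_and_detect(world, dropped$state, episode_cfg)
  if (outcome$unstable) {
    return(list(accepted = FALSE, reason = "unstable", config = target,
                start_state = dropped$state, outcome = outcome))
  }
  list(accepted = TRUE, reason = "ok", config = target,
       start_state = dropped$state, outcome = outcome)
}
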