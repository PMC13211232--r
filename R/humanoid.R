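# Default humanoid description: a 14-point rigid-link body (13 reported
# keypoints plus an internal neck anchor) with a rigid torso cluster and
# ball/hinge-jointed limbs. Local frame: +x toward the head, +y the subject's
# left, +z ventral (out of the chest); root at the pelvis centre. Segment
# lengths and masses approximate an adult lying figure.

#' Default humanoid model description
#'
#' Describes the rigid-link humanoid used by the physics world: keypoint
#' names and local torso coordinates, segment lengths, per-point masses, the
#' distance-constraint edge list that holds the body together, the kinematic
#' joint descriptors, and which points count as hands (the two most distal
#' upper-limb bodies — the wrists) for the fall-detection exclusion rule.
#'
#' @param model_id identifier of the humanoid variant; only
#'   `"default_humanoid"` is defined.
#' @return a list with elements `keypoint_names`, `point_names`, `local_torso`,
#'   `segments`, `masses`, `edges` (two-column index matrix, 1-based),
#'   `rest_lengths`, `joint_descriptors` (data.frame: name, kind, lower,
#'   upper), `hand_points`, `n_points`.
#' @export
humanoid_model <- function(model_id = "default_humanoid") {
  if (!identical(model_id, "default_humanoid")) {
    stop("unknown humanoid model id: ", model_id)
  }
  keypoint_names <- c(
    "head", "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "hip_l", "hip_r", "knee_l", "knee_r",
    "ankle_l", "ankle_r"
  )
  point_names <- c(keypoint_names, "neck")
  segments <- c(neck_head = 0.15, upper_arm = 0.28, forearm = 0.25,
                thigh = 0.40, shank = 0.40)
  local_torso <- rbind(
    shoulder_l = c(0.45, 0.17, 0),
    shoulder_r = c(0.45, -0.17, 0),
    hip_l = c(0.00, 0.10, 0),
    hip_r = c(0.00, -0.10, 0),
    neck = c(0.50, 0.00, 0)
  )
  masses <- c(
    head = 5, shoulder_l = 6, shoulder_r = 6, elbow_l = 2, elbow_r = 2,
    wrist_l = 1, wrist_r = 1, hip_l = 8, hip_r = 8, knee_l = 5, knee_r = 5,
    ankle_l = 3, ankle_r = 3, neck = 8
  )[point_names]

  idx <- function(nm) match(nm, point_names)
  torso_names <- rownames(local_torso)
  # rigid torso: complete graph over the 5 torso points
  torso_pairs <- t(utils::combn(torso_names, 2))
  edges_named <- rbind(
    torso_pairs,
    c("neck", "head"),
    c("shoulder_l", "elbow_l"), c("elbow_l", "wrist_l"),
    c("shoulder_r", "elbow_r"), c("elbow_r", "wrist_r"),
    c("hip_l", "knee_l"), c("knee_l", "ankle_l"),
    c("hip_r", "knee_r"), c("knee_r", "ankle_r")
  )
  edges <- cbind(idx(edges_named[, 1]), idx(edges_named[, 2]))
  torso_len <- function(a, b) sqrt(sum((local_torso[a, ] - local_torso[b, ])^2))
  rest <- c(
    mapply(torso_len, torso_pairs[, 1], torso_pairs[, 2]),
    segments[["neck_head"]],
    segments[["upper_arm"]], segments[["forearm"]],
    segments[["upper_arm"]], segments[["forearm"]],
    segments[["thigh"]], segments[["shank"]],
    segments[["thigh"]], segments[["shank"]]
  )

  joint_descriptors <- data.frame(
    name = c("neck", "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
             "hip_l", "hip_r", "knee_l", "knee_r"),
    kind = c("ball", "ball", "ball", "hinge", "hinge",
             "ball", "ball", "hinge", "hinge"),
    lower = c(NA, NA, NA, 0, 0, NA, NA, 0, 0),
    upper = c(NA, NA, NA, 2.6, 2.6, NA, NA, 2.6, 2.6),
    stringsAsFactors = FALSE
  )

  list(
    model_id = model_id,
    keypoint_names = keypoint_names,
    point_names = point_names,
    n_points = length(point_names),
    local_torso = local_torso,
    segments = segments,
    masses = unname(masses),
    edges = edges,
    rest_lengths = unname(rest),
    joint_descriptors = joint_descriptors,
    hand_points = idx(c("wrist_l", "wrist_r"))
  )
}

#' Identity (reset) joint configuration
#'
#' All ball joints at the identity quaternion and all hinges at zero: a
#' straight, arms-at-side reference pose.
#'
#' @param model a [humanoid_model()].
#' @return named list of joint values (unit quaternions for ball joints,
#'   scalars for hinges).
#' @export
reset_joints <- function(model) {
  jd <- model$joint_descriptors
  out <- vector("list", nrow(jd))
  names(out) <- jd$name
  for (i in seq_len(nrow(jd))) {
    out[[i]] <- if (jd$kind[i] == "ball") quat_identity() else 0
  }
  out
}

#' Forward kinematics of the humanoid
#'
#' Maps a minimal-coordinate configuration (root position, root orientation,
#' joint values) to the 3D positions of all body points. Limb segments extend
#' toward the feet (-x in their parent frame) in the reference pose; hinge
#' joints (elbows, knees) rotate about the local y axis.
#'
#' @param model a [humanoid_model()].
#' @param root_pos length-3 world position of the pelvis centre.
#' @param root_quat unit quaternion of the root orientation.
#' @param joints named list of joint values as in [reset_joints()].
#' @return `n_points` x 3 matrix of world positions, rows named by point.
#' @export
fk_pose <- function(model, root_pos, root_quat, joints) {
  Rr <- quat_to_matrix(root_quat)
  P <- matrix(NA_real_, model$n_points, 3,
              dimnames = list(model$point_names, NULL))
  for (nm in rownames(model$local_torso)) {
    P[nm, ] <- root_pos + as.vector(Rr %*% model$local_torso[nm, ])
  }
  seg <- model$segments
  down <- function(len) c(-len, 0, 0)

  F_neck <- Rr %*% quat_to_matrix(joints$neck)
  P["head", ] <- P["neck", ] + as.vector(F_neck %*% c(seg[["neck_head"]], 0, 0))

  for (side in c("l", "r")) {
    sh <- paste0("shoulder_", side); el <- paste0("elbow_", side)
    wr <- paste0("wrist_", side)
    F_sh <- Rr %*% quat_to_matrix(joints[[paste0("shoulder_", side)]])
    P[el, ] <- P[sh, ] + as.vector(F_sh %*% down(seg[["upper_arm"]]))
    F_el <- F_sh %*% quat_to_matrix(
      quat_axis_angle(c(0, 1, 0), joints[[paste0("elbow_", side)]]))
    P[wr, ] <- P[el, ] + as.vector(F_el %*% down(seg[["forearm"]]))

    hp <- paste0("hip_", side); kn <- paste0("knee_", side)
    an <- paste0("ankle_", side)
    F_hip <- Rr %*% quat_to_matrix(joints[[paste0("hip_", side)]])
    P[kn, ] <- P[hp, ] + as.vector(F_hip %*% down(seg[["thigh"]]))
    F_kn <- F_hip %*% quat_to_matrix(
      quat_axis_angle(c(0, 1, 0), joints[[paste0("knee_", side)]]))
    P[an, ] <- P[kn, ] + as.vector(F_kn %*% down(seg[["shank"]]))
  }
  P
}
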