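# Initial-state sampling: planar position on the bed, root orientation
# (pose-stratified over four lying-posture presets, or fully random), and
# joint angles. All randomness goes through R's RNG so whole sampling streams
# are reproducible from a single seed.

#' Posture-mode orientation presets
#'
#' The four coarse lying postures as root Euler triples (radians, intrinsic
#' XYZ): supine lies back-down with the head along the bed's long (+x) axis;
#' prone is its 180 degree roll; the laterals are the -90/+90 degree rolls
#' (left-lateral = left side down).
#'
#' @return named list of length-3 Euler triples `(roll, pitch, yaw)`.
#' @export
posture_presets <- function() {
  list(
    supine = c(0, 0, 0),
    prone = c(pi, 0, 0),
    left_lateral = c(-pi / 2, 0, 0),
    right_lateral = c(pi / 2, 0, 0)
  )
}

#' Names of the four posture modes
#' @return character vector of length 4.
#' @export
posture_modes <- function() names(posture_presets())

#' Sampler configuration
#'
#' @param strategy `"pose_stratified"` (uniform over the four posture presets
#'   with Gaussian Euler perturbation) or `"fully_random"` (independent
#'   uniform Euler angles on \[-180, 180\] degrees per axis).
#' @param sigma_deg standard deviation, degrees per axis, of the zero-mean
#'   Gaussian perturbation applied to the preset Euler angles (default 15).
#' @param edge_margin metres kept from the bed edges when sampling the planar
#'   position (default 0.1).
#' @param joint_range_default half-range, radians, for hinge joints without
#'   declared limits (default pi/4).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(strategy = c("pose_stratified", "fully_random"),
                           sigma_deg = 15,
                           edge_margin = 0.1,
                           joint_range_default = pi / 4) {
  strategy <- match.arg(strategy)
  if (sigma_deg < 0) stop("sigma_deg must be >= 0")
  if (edge_margin < 0) stop("edge_margin must be >= 0")
  structure(list(strategy = strategy, sigma_deg = sigma_deg,
                 edge_margin = edge_margin,
                 joint_range_default = joint_range_default),
            class = "sampler_config")
}

#' Sample a planar position on the bed
#'
#' Uniform on the bed footprint shrunk by `edge_margin` on every side.
#'
#' @param bounds bed bounds (list with `x_min`, `x_max`, `y_min`, `y_max`).
#' @param edge_margin margin from the bed edges, metres.
#' @return length-2 numeric `(x, y)` in the bed frame.
#' @export
sample_planar_position <- function(bounds, edge_margin = 0.1) {
  xlo <- bounds$x_min + edge_margin; xhi <- bounds$x_max - edge_margin
  ylo <- bounds$y_min + edge_margin; yhi <- bounds$y_max - edge_margin
  if (xlo > xhi || ylo > yhi) {
    stop("edge_margin leaves an empty feasible region on the bed")
  }
  c(runif(1, xlo, xhi), runif(1, ylo, yhi))
}

#' Sample a root orientation
#'
#' Pose-stratified: the preset Euler triple of `mode` plus independent
#' zero-mean Gaussian perturbations of `sigma_deg` degrees per axis. Fully
#' random: independent uniform Euler angles on \[-180, 180\] degrees per axis.
#' Either way the Euler triple is converted to a unit quaternion. Note that
#' uniform Euler angles do not induce uniform rotations; the fully-random
#' strategy deliberately samples uniform Euler angles.
#'
#' @param config a [sampler_config()].
#' @param mode posture mode name, required iff the strategy is
#'   `pose_stratified`.
#' @return unit quaternion `(w, x, y, z)`.
#' @export
sample_root_orientation <- function(config, mode = NULL) {
  if (config$strategy == "pose_stratified") {
    if (is.null(mode)) stop("pose_stratified sampling requires a posture mode")
    preset <- posture_presets()[[mode]]
    if (is.null(preset)) stop("unknown posture mode: ", mode)
    eul <- preset + rnorm(3, 0, config$sigma_deg * pi / 180)
  } else {
    if (!is.null(mode)) stop("fully_random sampling takes no posture mode")
    eul <- runif(3, -pi, pi)
  }
  quat_normalize(quat_from_euler(eul[1], eul[2], eul[3]))
}

#' Sample joint angles
#'
#' Hinge joints are drawn uniformly within their declared limits, or on
#' `[-joint_range_default, joint_range_default]` when unlimited; ball joints
#' are drawn as uniform random unit quaternions (uniform on the rotation
#' group).
#'
#' @param joint_descriptors data.frame with `name`, `kind` (`"ball"` or
#'   `"hinge"`), `lower`, `upper` (radians, `NA` = unlimited).
#' @param config a [sampler_config()].
#' @return named list of joint values.
#' @export
sample_joint_angles <- function(joint_descriptors, config) {
  out <- vector("list", nrow(joint_descriptors))
  names(out) <- joint_descriptors$name
  for (i in seq_len(nrow(joint_descriptors))) {
    if (joint_descriptors$kind[i] == "ball") {
      out[[i]] <- quat_random_uniform()
    } else {
      lo <- joint_descriptors$lower[i]
      hi <- joint_descriptors$upper[i]
      if (is.na(lo) || is.na(hi)) {
        lo <- -config$joint_range_default
        hi <- config$joint_range_default
      }
      out[[i]] <- if (hi > lo) runif(1, lo, hi) else lo
    }
  }
  out
}

#' Sample a full initial configuration
#'
#' Composes the planar-position, root-orientation, and joint-angle samplers.
#' Under pose-stratified sampling the posture mode is drawn uniformly over
#' the four modes (or forced with `force_mode`, used when building
#' pose-balanced sets) and recorded on the output; under fully-random
#' sampling the mode is `NA`.
#'
#' @param config a [sampler_config()].
#' @param bounds bed bounds.
#' @param joint_descriptors joint descriptor table (see
#'   [sample_joint_angles()]).
#' @param force_mode optional posture mode overriding the uniform mode draw
#'   (pose-stratified only).
#' @return an `initial_configuration` list with `planar_xy`, `root_quat`,
#'   `joints`, `mode`.
#' @export
sample_initial_configuration <- function(config, bounds, joint_descriptors,
                                         force_mode = NULL) {
  if (config$strategy == "pose_stratified") {
    mode <- if (is.null(force_mode)) {
      posture_modes()[sample.int(4L, 1L)]
    } else {
      stopifnot(force_mode %in% posture_modes())
      force_mode
    }
  } else {
    mode <- NA_character_
  }
  planar_xy <- sample_planar_position(bounds, config$edge_margin)
  root_quat <- sample_root_orientation(
    config, mode = if (is.na(mode)) NULL else mode)
  joints <- sample_joint_angles(joint_descriptors, config)
  structure(list(planar_xy = planar_xy, root_quat = root_quat,
                 joints = joints, mode = mode),
            class = "initial_configuration")
}
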