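# 13-keypoint 2D skeleton extraction, bed-bounds normalization to [-1, 1]^2,
# validity flags, and flattening to the 26-D feature vector.
#
# Fixed keypoint order (frozen, also used in the CSV header):
# head, L/R shoulder, L/R elbow, L/R wrist, L/R hip, L/R knee, L/R ankle.
# The flattened vector interleaves coordinates per keypoint:
# u = (x_1, y_1, ..., x_13, y_13).

#' Extract the raw 2D skeleton from a simulator state
#'
#' Planar projection (the vertical axis is dropped) of the 13 configured
#' body-point anchors, in the fixed keypoint order.
#'
#' @param world a `bedfall_world`.
#' @param state a `sim_state`.
#' @return 13 x 2 matrix of planar coordinates in metres (bed frame), rows
#'   named by keypoint.
#' @export
extract_keypoints <- function(world, state) {
  stopifnot(inherits(state, "sim_state"))
  if (!state_is_finite(state)) stop("cannot extract keypoints: state not finite")
  kp <- world$model$keypoint_names
  idx <- match(kp, world$model$point_names)
  if (anyNA(idx)) stop("humanoid description is missing a keypoint anchor")
  out <- state$pos[idx, 1:2, drop = FALSE]
  rownames(out) <- kp
  colnames(out) <- c("x", "y")
  out
}

#' Normalize a raw skeleton to the bed bounds
#'
#' Per-axis affine map sending the bed footprint rectangle to `[-1, 1]^2`:
#' `x' = 2 (x - x_min) / (x_max - x_min) - 1`, and likewise for y. Validity
#' flags are 1 iff both raw coordinates lie within the bed bounds;
#' out-of-bounds keypoints retain their affine image (which exceeds +-1).
#'
#' @param raw 13 x 2 raw skeleton matrix (metres).
#' @param bounds bed bounds (list with `x_min < x_max`, `y_min < y_max`).
#' @return list with `coords` (13 x 2 normalized) and `valid` (13 integer
#'   flags).
#' @export
normalize_skeleton <- function(raw, bounds) {
  stopifnot(is.matrix(raw), ncol(raw) == 2)
  if (!(bounds$x_min < bounds$x_max && bounds$y_min < bounds$y_max)) {
    stop("degenerate bed bounds")
  }
  xs <- 2 * (raw[, 1] - bounds$x_min) / (bounds$x_max - bounds$x_min) - 1
  ys <- 2 * (raw[, 2] - bounds$y_min) / (bounds$y_max - bounds$y_min) - 1
  valid <- as.integer(
    raw[, 1] >= bounds$x_min & raw[, 1] <= bounds$x_max &
    raw[, 2] >= bounds$y_min & raw[, 2] <= bounds$y_max)
  coords <- cbind(x = xs, y = ys)
  rownames(coords) <- rownames(raw)
  list(coords = coords, valid = valid)
}

#' Invert the bed-bounds normalization
#'
#' @param coords 13 x 2 normalized coordinates.
#' @param bounds bed bounds.
#' @return 13 x 2 raw coordinates in metres.
#' @export
denormalize_skeleton <- function(coords, bounds) {
  xs <- (coords[, 1] + 1) / 2 * (bounds$x_max - bounds$x_min) + bounds$x_min
  ys <- (coords[, 2] + 1) / 2 * (bounds$y_max - bounds$y_min) + bounds$y_min
  cbind(x = xs, y = ys)
}

#' Flatten a normalized skeleton to the 26-D feature vector
#'
#' Interleaved order `(x_1, y_1, ..., x_13, y_13)` in the fixed keypoint
#' order; exactly invertible with [unflatten_skeleton()].
#'
#' @param coords 13 x 2 normalized coordinate matrix.
#' @return numeric vector of length 26.
#' @export
flatten_skeleton <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) == 13, ncol(coords) == 2)
  as.vector(t(coords))
}

#' Reconstruct a normalized skeleton from a 26-D feature vector
#'
#' @param u numeric vector of length 26.
#' @return 13 x 2 coordinate matrix.
#' @export
unflatten_skeleton <- function(u) {
  stopifnot(length(u) == 26)
  matrix(u, ncol = 2, byrow = TRUE,
         dimnames = list(humanoid_model()$keypoint_names, c("x", "y")))
}

# full extraction pipeline: state -> (u, v)
state_to_features <- function(world, state) {
  raw <- extract_keypoints(world, state)
  norm <- normalize_skeleton(raw, bed_bounds(world))
  list(u = flatten_skeleton(norm$coords), v = norm$valid)
}

# raw 13x2 planar frame snapshot (as returned by the rollout) -> 26-vector
frame_to_features <- function(frame_row, bounds) {
  raw <- matrix(frame_row, ncol = 2, byrow = TRUE)
  flatten_skeleton(normalize_skeleton(raw, bounds)$coords)
}
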