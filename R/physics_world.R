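# The physics world: a floor plane at z = 0, one box bed, one humanoid.
# All other modules talk to this contract (build_world / step_world / freeze),
# never to the engine internals directly.

#' World configuration
#'
#' @param bed_extents length/width/height of the box bed in metres
#'   (default 2.0 x 0.9 x 0.5, typical single-bed geometry).
#' @param bed_top_height height of the bed top face above the floor; defaults
#'   to the bed height (bed resting on the floor).
#' @param sim_timestep simulator timestep in seconds.
#' @param gravity downward gravitational acceleration, m/s^2.
#' @param humanoid_model_id identifier passed to [humanoid_model()].
#' @param friction static/kinetic friction coefficients for floor and bed-top
#'   contacts.
#' @param contact_radius contact radius of each body point, metres.
#' @param solver_iters constraint-projection iterations per step.
#' @param velocity_damping per-step velocity damping fraction.
#' @return a `world_config` list.
#' @export
world_config <- function(bed_extents = c(2.0, 0.9, 0.5),
                         bed_top_height = bed_extents[3],
                         sim_timestep = 0.005,
                         gravity = 9.81,
                         humanoid_model_id = "default_humanoid",
                         friction = c(static = 0.7, kinetic = 0.5),
                         contact_radius = 0.04,
                         solver_iters = 10,
                         velocity_damping = 0.002) {
  cfg <- list(
    bed_extents = bed_extents, bed_top_height = bed_top_height,
    sim_timestep = sim_timestep, gravity = gravity,
    humanoid_model_id = humanoid_model_id, friction = friction,
    contact_radius = contact_radius, solver_iters = solver_iters,
    velocity_damping = velocity_damping
  )
  if (length(bed_extents) != 3 || any(!is.finite(bed_extents)) ||
      any(bed_extents <= 0)) {
    stop("bed_extents must be three positive numbers")
  }
  if (!is.finite(sim_timestep) || sim_timestep <= 0) {
    stop("sim_timestep must be positive")
  }
  if (bed_top_height < bed_extents[3]) {
    stop("bed must fit above the floor (bed_top_height >= bed height)")
  }
  class(cfg) <- "world_config"
  cfg
}

#' Build the bed--human world
#'
#' Assembles the steppable world: floor plane, one box bed centred at the
#' planar origin (long axis along x), and one humanoid. The bed-bounds
#' rectangle equals the bed top face footprint and is queryable with
#' [bed_bounds()].
#'
#' @param config a [world_config()].
#' @return a `bedfall_world` object.
#' @export
build_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  model <- humanoid_model(config$humanoid_model_id)
  half <- config$bed_extents / 2
  bounds <- list(x_min = -half[1], x_max = half[1],
                 y_min = -half[2], y_max = half[2])
  hand <- integer(model$n_points)
  hand[model$hand_points] <- 1L
  engine_params <- list(
    invmass = 1 / model$masses,
    edge_a = as.integer(model$edges[, 1] - 1L),
    edge_b = as.integer(model$edges[, 2] - 1L),
    rest = model$rest_lengths,
    bed = c(bounds$x_min, bounds$x_max, bounds$y_min, bounds$y_max,
            config$bed_top_height),
    dt = config$sim_timestep,
    gravity = config$gravity,
    mu_static = unname(config$friction["static"]),
    mu_kinetic = unname(config$friction["kinetic"]),
    damping = config$velocity_damping,
    radius = config$contact_radius,
    iters = as.integer(config$solver_iters),
    hand = hand
  )
  structure(
    list(config = config, model = model, bounds = bounds,
         engine_params = engine_params,
         entities = c("floor", "bed", "humanoid")),
    class = "bedfall_world"
  )
}

#' Bed top-face footprint rectangle
#'
#' @param world a [build_world()] world.
#' @return list with `x_min`, `x_max`, `y_min`, `y_max` in metres.
#' @export
bed_bounds <- function(world) {
  stopifnot(inherits(world, "bedfall_world"))
  world$bounds
}

#' Construct a simulation state
#'
#' The engine uses maximal coordinates: per-point positions and velocities
#' plus the simulation clock.
#'
#' @param pos n_points x 3 matrix of world positions.
#' @param vel n_points x 3 matrix of velocities (default zero).
#' @param t simulation time in seconds.
#' @return a `sim_state` object.
#' @export
sim_state <- function(pos, vel = matrix(0, nrow(pos), 3), t = 0) {
  stopifnot(is.matrix(pos), ncol(pos) == 3, identical(dim(pos), dim(vel)))
  structure(list(pos = pos, vel = vel, t = t), class = "sim_state")
}

state_is_finite <- function(state) {
  all(is.finite(state$pos)) && all(is.finite(state$vel))
}

# engine contact codes -> classified contact events
contacts_from_codes <- function(world, codes) {
  model <- world$model
  rows <- list()
  for (i in seq_along(codes)) {
    nm <- model$point_names[i]
    if (bitwAnd(codes[i], 1L) != 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        body_a = nm, body_b = "bed", kind = "humanoid-bed",
        stringsAsFactors = FALSE)
    }
    if (bitwAnd(codes[i], 2L) != 0L) {
      kind <- if (i %in% model$hand_points) "hand-floor" else "humanoid-floor"
      rows[[length(rows) + 1L]] <- data.frame(
        body_a = nm, body_b = "floor", kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(body_a = character(), body_b = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Advance the world by one timestep
#'
#' Advances the clock by exactly one `sim_timestep` and returns all contacts
#' active after the step, each classified as `humanoid-bed`,
#' `humanoid-floor`, or `hand-floor` (a wrist against the floor).
#'
#' @param world a `bedfall_world`.
#' @param state a `sim_state`.
#' @return list with `state` (advanced) and `contacts` (data.frame with
#'   `body_a`, `body_b`, `kind`). If the engine diverges, the returned state
#'   carries `unstable = TRUE` and the episode must be discarded.
#' @export
step_world <- function(world, state) {
  stopifnot(inherits(world, "bedfall_world"), inherits(state, "sim_state"))
  if (!state_is_finite(state)) {
    out <- state
    out$unstable <- TRUE
    return(list(state = out, contacts = contacts_from_codes(world, integer(0))))
  }
  res <- eng_step(state$pos, state$vel, world$engine_params)
  dt <- world$config$sim_timestep
  tick <- round(state$t / dt) + 1  # exact clock: t is always a step multiple
  new_state <- sim_state(res$P, res$V, t = tick * dt)
  rownames(new_state$pos) <- rownames(state$pos)
  rownames(new_state$vel) <- rownames(state$vel)
  if (isTRUE(res$unstable)) new_state$unstable <- TRUE
  list(state = new_state, contacts = contacts_from_codes(world, res$contact))
}

#' Freeze the dynamics of a state
#'
#' Zeroes all velocities (and controls; the rollout is uncontrolled so there
#' are none) and resets the simulation clock to zero, keeping positions
#' untouched. Used to standardise the episode start at first bed contact.
#'
#' @param world a `bedfall_world`.
#' @param state a `sim_state`.
#' @return the frozen `sim_state` with zero velocity and `t = 0`.
#' @export
freeze <- function(world, state) {
  stopifnot(inherits(state, "sim_state"))
  out <- sim_state(state$pos, matrix(0, nrow(state$pos), 3), t = 0)
  rownames(out$pos) <- rownames(state$pos)
  out
}

#' Serialize the world description as an XML model document
#'
#' Writes the world geometry (floor, bed box, humanoid points / links) as a
#' simple XML document, generated programmatically from the configuration.
#'
#' @param world a `bedfall_world`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_world_xml <- function(world, path) {
  cfg <- world$config
  model <- world$model
  esc <- function(x) format(x, digits = 17)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<world engine="bedfall-pbd">',
    sprintf('  <option timestep="%s" gravity="%s"/>',
            esc(cfg$sim_timestep), esc(cfg$gravity)),
    '  <geom name="floor" type="plane" height="0"/>',
    sprintf('  <geom name="bed" type="box" extents="%s %s %s" top="%s"/>',
            esc(cfg$bed_extents[1]), esc(cfg$bed_extents[2]),
            esc(cfg$bed_extents[3]), esc(cfg$bed_top_height)),
    sprintf('  <humanoid model="%s">', model$model_id),
    vapply(seq_len(model$n_points), function(i) {
      sprintf('    <point name="%s" mass="%s" hand="%d"/>',
              model$point_names[i], esc(model$masses[i]),
              as.integer(i %in% model$hand_points))
    }, character(1)),
    vapply(seq_len(nrow(model$edges)), function(e) {
      sprintf('    <link a="%s" b="%s" length="%s"/>',
              model$point_names[model$edges[e, 1]],
              model$point_names[model$edges[e, 2]],
              esc(model$rest_lengths[e]))
    }, character(1)),
    '  </humanoid>',
    '</world>'
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records timestep, gravity, geometry, friction, and package version as JSON
#' so a dataset can be reproduced from (seed, configs, engine build).
#'
#' @param world a `bedfall_world`.
#' @param path output JSON path.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(world, path, extra = list()) {
  cfg <- world$config
  manifest <- c(list(
    engine = "bedfall-pbd",
    package_version = as.character(utils::packageVersion("bedfall")),
    sim_timestep = cfg$sim_timestep,
    gravity = cfg$gravity,
    bed_extents = cfg$bed_extents,
    bed_top_height = cfg$bed_top_height,
    friction = as.list(cfg$friction),
    contact_radius = cfg$contact_radius,
    solver_iters = cfg$solver_iters,
    velocity_damping = cfg$velocity_damping,
    humanoid_model_id = cfg$humanoid_model_id,
    euler_convention = "intrinsic XYZ (roll-pitch-yaw)",
    bed_frame = "bed centre is the planar origin; long axis = x"
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
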