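# Physics-free surrogate data generator. Emulates the statistical structure
# of the simulated datasets — coherent 13-point skeletons in bed-normalized
# coordinates with fall risk tied monotonically to proximity of the body to
# the bed edges — so that models, the evaluator and the I/O layer are
# testable in seconds without the engine. Labels are computed by the real
# risk-labelling code path, so they satisfy all its invariants.

#' Surrogate generator configuration
#'
#' @param n_samples number of samples to generate.
#' @param edge_cutoff normalized signed edge distance below which an episode
#'   "falls" (default 0.05): skeletons whose closest keypoint is within this
#'   distance of (or beyond) a bed edge are fall cases.
#' @param deep_overhang normalized distance beyond the edge mapped to an
#'   immediate fall (frame 0); the fall frame grows linearly from 0 at
#'   `-deep_overhang` to the last frame at `edge_cutoff` (default 0.2).
#' @param noise_sd coordinate jitter added to each keypoint (default 0.02).
#' @param label_cfg a [label_config()] reused for the labels.
#' @param balanced draw exactly half fall / half non-fall samples.
#' @return a `surrogate_config` list.
#' @export
surrogate_config <- function(n_samples = 1000, edge_cutoff = 0.05,
                             deep_overhang = 0.2, noise_sd = 0.02,
                             label_cfg = label_config(), balanced = TRUE) {
  stopifnot(n_samples >= 1, edge_cutoff > -1, deep_overhang > 0,
            noise_sd >= 0)
  structure(list(n_samples = n_samples, edge_cutoff = edge_cutoff,
                 deep_overhang = deep_overhang, noise_sd = noise_sd,
                 label_cfg = label_cfg, balanced = balanced),
            class = "surrogate_config")
}

# one coherent 13-point chain in normalized coordinates
surrogate_skeleton <- function(center, phi, noise_sd) {
  dir <- c(cos(phi), sin(phi))
  perp <- c(-sin(phi), cos(phi))
  at <- function(a, p) center + a * dir + p * perp
  base <- rbind(
    head = at(0.55, 0),
    shoulder_l = at(0.38, 0.15), shoulder_r = at(0.38, -0.15),
    elbow_l = at(0.18, 0.22), elbow_r = at(0.18, -0.22),
    wrist_l = at(-0.02, 0.26), wrist_r = at(-0.02, -0.26),
    hip_l = at(0, 0.09), hip_r = at(0, -0.09),
    knee_l = at(-0.33, 0.11), knee_r = at(-0.33, -0.11),
    ankle_l = at(-0.66, 0.12), ankle_r = at(-0.66, -0.12)
  )
  base + matrix(rnorm(26, 0, noise_sd), 13, 2)
}

# signed distance of the skeleton to the nearest bed edge of [-1, 1]^2
# (negative when a keypoint lies outside the footprint)
surrogate_edge_distance <- function(coords) {
  min(1 - pmax(abs(coords[, 1]), abs(coords[, 2])))
}

surrogate_outcome <- function(d, cfg) {
  if (d >= cfg$edge_cutoff) {
    return(list(fell = FALSE, fall_step = NA_integer_, unstable = FALSE))
  }
  lc <- cfg$label_cfg
  max_frame <- floor(lc$fps * lc$window)  # last frame of the window
  frac <- (d + cfg$deep_overhang) / (cfg$edge_cutoff + cfg$deep_overhang)
  n_f <- as.integer(round(max_frame * min(1, max(0, frac))))
  # convert the fall frame back to a simulator step on the labelling grid
  s_f <- as.integer(ceiling(n_f / (lc$fps * lc$sim_timestep)))
  list(fell = TRUE, fall_step = s_f, unstable = FALSE)
}

#' Generate a surrogate dataset
#'
#' Skeletons are coherent 13-point chains placed inside/near the normalized
#' bed square; an episode falls iff its minimum signed keypoint distance to
#' the nearest bed edge is below the cutoff, with the fall frame increasing
#' with that distance. Labels are computed by the real risk labeller, so
#' they lie in `{0}` union `[gamma^(fps*window), 1]` and risk never
#' decreases as edge distance shrinks.
#'
#' @param config a [surrogate_config()].
#' @param seed RNG seed.
#' @return a dataset data.frame in the same schema as
#'   [build_balanced_dataset()] (mode tags from the orientation quadrant;
#'   `episode_seed` is the draw index).
#' @export
generate_surrogate <- function(config = surrogate_config(), seed = 1) {
  stopifnot(inherits(config, "surrogate_config"))
  set.seed(seed)
  lc <- config$label_cfg
  n <- config$n_samples
  quota <- if (config$balanced) {
    c(fall = ceiling(n / 2), nonfall = floor(n / 2))
  } else {
    c(fall = n, nonfall = n)  # no per-class cap
  }
  got <- c(fall = 0L, nonfall = 0L)
  rows <- list()
  draw <- 0L
  while (length(rows) < n) {
    draw <- draw + 1L
    if (draw > 1000 * n) stop("surrogate draw budget exhausted")
    center <- runif(2, -0.85, 0.85)
    phi <- runif(1, -pi, pi)
    coords <- surrogate_skeleton(center, phi, config$noise_sd)
    d <- surrogate_edge_distance(coords)
    outcome <- surrogate_outcome(d, config)
    cls <- if (outcome$fell) "fall" else "nonfall"
    if (config$balanced && got[cls] >= quota[cls]) next
    got[cls] <- got[cls] + 1L
    y <- risk_label(outcome, lc)
    mode <- posture_modes()[1 + (floor((phi + pi) / (pi / 2)) %% 4)]
    bounds <- list(x_min = -1, x_max = 1, y_min = -1, y_max = 1)
    norm <- normalize_skeleton(coords, bounds)
    row <- data.frame(mode = mode, c = as.integer(outcome$fell), y = y,
                      stringsAsFactors = FALSE)
    row[u_cols()] <- as.list(flatten_skeleton(norm$coords))
    row[v_cols()] <- as.list(norm$valid)
    row$episode_seed <- draw
    rows[[length(rows) + 1L]] <- row
  }
  new_dataset(rows, lc, list(x_min = -1, x_max = 1, y_min = -1, y_max = 1),
              stats = list(draws = draw))
}
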