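# Discounted time-to-fall risk labels on a fixed 30 fps temporal grid,
# independent of the internal simulator frequency.

#' Label configuration
#'
#' @param fps frames per second of the labelling grid (default 30).
#' @param gamma per-frame discount factor in (0, 1), defined on the fps grid
#'   (default 0.99).
#' @param sim_timestep simulator timestep in seconds.
#' @param window rollout window T in seconds (default 3.0).
#' @return a `label_config` list.
#' @export
label_config <- function(fps = 30, gamma = 0.99, sim_timestep = 0.005,
                         window = 3.0) {
  if (!(gamma > 0 && gamma < 1)) stop("gamma must lie strictly in (0, 1)")
  if (fps <= 0 || sim_timestep <= 0 || window <= 0) {
    stop("fps, sim_timestep and window must be positive")
  }
  structure(list(fps = fps, gamma = gamma, sim_timestep = sim_timestep,
                 window = window),
            class = "label_config")
}

#' Convert a simulator step index to a frame index
#'
#' `n = floor(fps * s * sim_timestep)`: the last completed frame on the fps
#' grid at simulator step `s` (floor chosen for non-grid-aligned steps; the
#' induced sensitivity is at most one frame).
#'
#' @param s non-negative simulator step index (vectorised).
#' @param config a [label_config()].
#' @return non-negative integer frame index.
#' @export
step_to_frame <- function(s, config) {
  if (any(s < 0)) stop("step index must be non-negative")
  as.integer(floor(config$fps * s * config$sim_timestep + 1e-9))
}

#' Continuous risk label from an episode outcome
#'
#' For a fall first detected at simulator step `s_f`, an observation at step
#' `s` receives `y = gamma^(n_f - n(s))` with frame indices from
#' [step_to_frame()]; episodes with no fall inside the window receive exactly
#' 0. The main pipeline always observes the initial state (`s = 0`), giving
#' `y = gamma^(n_f)`.
#'
#' @param outcome an `episode_outcome` (must not be unstable).
#' @param config a [label_config()].
#' @param observe_step simulator step of the observation (default 0).
#' @return risk label in `{0}` union `[gamma^(fps*window), 1]`.
#' @export
risk_label <- function(outcome, config, observe_step = 0) {
  if (isTRUE(outcome$unstable)) {
    stop("refusing to label an unstable episode")
  }
  if (!isTRUE(outcome$fell)) return(0)
  if (observe_step > outcome$fall_step) {
    stop("observation step lies after the fall")
  }
  n_f <- step_to_frame(outcome$fall_step, config)
  n_s <- step_to_frame(observe_step, config)
  config$gamma^(n_f - n_s)
}

#' Hazard rate equivalent of the per-frame discount
#'
#' The discounted label is a monotone exponential transform of remaining
#' time-to-fall: `gamma^(n_f - n) = exp(-lambda * (n_f - n) / fps)` with
#' `lambda = -fps * log(gamma)` per second.
#'
#' @param config a [label_config()].
#' @return hazard rate lambda in 1/seconds.
#' @export
hazard_rate <- function(config) {
  -config$fps * log(config$gamma)
}

#' Smallest attainable fall label
#'
#' `gamma^(fps * window)`: the label of a fall at the last frame of the
#' rollout window (about 0.405 with the defaults gamma = 0.99, 30 fps, 3 s).
#'
#' @param config a [label_config()].
#' @return lower bound of the fall-label range.
#' @export
min_fall_label <- function(config) {
  config$gamma^(config$fps * config$window)
}
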