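#' Parameters for synthetic spike-train recordings
#'
#' Homogeneous-Poisson units recorded over alternating stimulation blocks
#' (6 s blocks, 1 s inter-block gaps, laser on half the blocks). Each
#' unit's ground-truth laser modulation index `m` determines its
#' laser-block rate by inverting the index definition:
#' `r_laser = r_baseline * (1 + m) / (1 - m)` (with `m = 1` mapped to a
#' large finite rate and `m = -1` to silence).
#'
#' @param n_units Number of units.
#' @param baseline_rate_hz Baseline (non-laser) rate per unit; recycled.
#' @param modulation_index Ground-truth index per unit in \[-1, 1\];
#'   recycled.
#' @param block_s Block duration (default 6).
#' @param interblock_s Gap between blocks (default 1).
#' @param laser_block_fraction Fraction of laser blocks (default 0.5).
#' @return A `spike_sim_params` list.
#' @export
spike_sim_params <- function(n_units = 20, baseline_rate_hz = 5,
                             modulation_index = 0, block_s = 6,
                             interblock_s = 1,
                             laser_block_fraction = 0.5) {
  baseline_rate_hz <- rep_len(baseline_rate_hz, n_units)
  modulation_index <- rep_len(modulation_index, n_units)
  stopifnot(all(baseline_rate_hz >= 0), all(abs(modulation_index) <= 1),
            block_s > 0, interblock_s >= 0)
  if (any(modulation_index == -1 & baseline_rate_hz == 0)) {
    stop_bad_arg("index -1 with zero baseline is undefined")
  }
  structure(
    list(n_units = n_units, baseline_rate_hz = baseline_rate_hz,
         modulation_index = modulation_index, block_s = block_s,
         interblock_s = interblock_s,
         laser_block_fraction = laser_block_fraction),
    class = "spike_sim_params"
  )
}

# Laser rate implied by a baseline rate and target modulation index.
laser_rate_from_index <- function(r_baseline, m) {
  if_else(m >= 1, r_baseline * 1e6,
          r_baseline * (1 + m) / (1 - m))
}

#' Simulate spike trains over laser and non-laser blocks
#'
#' Draws homogeneous Poisson spikes per block; laser blocks use the rate
#' implied by each unit's ground-truth modulation index.
#'
#' @param params A [spike_sim_params()].
#' @param n_blocks Total number of blocks (even; half are laser).
#' @param seed Optional integer seed.
#' @return A list: `spikes` tibble (`unit_id`, `t_s`), `blocks` tibble
#'   (`start`, `end`, `laser`), `ground_truth` tibble.
#' @export
simulate_spike_trains <- function(params = spike_sim_params(),
                                  n_blocks = 40, seed = NULL) {
  stopifnot(n_blocks >= 2, n_blocks %% 2 == 0)
  with_seed(seed, {
    period <- params$block_s + params$interblock_s
    start <- (seq_len(n_blocks) - 1) * period
    laser <- sample(rep(c(TRUE, FALSE), n_blocks / 2))
    blocks <- tibble(start = start, end = start + params$block_s,
                     laser = laser)
    spikes <- list()
    for (u in seq_len(params$n_units)) {
      r_nl <- params$baseline_rate_hz[u]
      r_l <- laser_rate_from_index(r_nl, params$modulation_index[u])
      rate <- if_else(blocks$laser, r_l, r_nl)
      counts <- rpois(n_blocks, rate * params$block_s)
      t_s <- unlist(map(seq_len(n_blocks), function(b) {
        sort(runif(counts[b], blocks$start[b], blocks$end[b]))
      }), use.names = FALSE)
      spikes[[u]] <- tibble(unit_id = u, t_s = t_s)
    }
    list(
      spikes = bind_rows(spikes),
      blocks = blocks,
      ground_truth = tibble(unit_id = seq_len(params$n_units),
                            baseline_rate_hz = params$baseline_rate_hz,
                            modulation_index = params$modulation_index)
    )
  })
}

#' Laser modulation across a simulated or recorded unit set
#'
#' Convenience wrapper running [laser_modulation()] for every unit of a
#' spike table against a shared block table.
#'
#' @param spikes A tibble with `unit_id` and `t_s`.
#' @param blocks A tibble with `start`, `end`, `laser`.
#' @param alpha Block-wise test level (default 0.05).
#' @return A tibble with one [laser_modulation()] row per unit.
#' @export
unit_modulation_table <- function(spikes, blocks, alpha = 0.05) {
  laser_blocks <- blocks[blocks$laser, c("start", "end")]
  nonlaser_blocks <- blocks[!blocks$laser, c("start", "end")]
  units <- sort(unique(spikes$unit_id))
  list_rbind(map(units, function(u) {
    res <- laser_modulation(spikes$t_s[spikes$unit_id == u],
                            laser_blocks, nonlaser_blocks, alpha = alpha)
    mutate(res, unit_id = u, .before = 1)
  }))
}

#' Parameters for synthetic pose clips
#'
#' A turning mouse seen from below: an anchor (tail base or headplate), a
#' nose sweeping through a turn of the given direction, and two forepaws
#' offset laterally from the body axis by `paw_offset` (+ = animal's
#' right) with added coordinate noise, at 30 frames per second.
#'
#' @param turn_direction `"left"` or `"right"`.
#' @param paw_offset Lateral paw offset in pixels, + = animal's right.
#' @param body_angle_drift Total body-axis rotation over the clip
#'   (radians; sign set by `turn_direction` when 0 is passed a default
#'   0.8 rad sweep is used).
#' @param noise_sd Coordinate noise SD in pixels.
#' @param n_frames Frames in the clip (default 60, i.e. 2 s).
#' @param body_length Anchor-to-nose distance in pixels (default 120).
#' @param frame_rate_hz Default 30.
#' @return A `pose_sim_params` list.
#' @export
pose_sim_params <- function(turn_direction = c("left", "right"),
                            paw_offset = 10, body_angle_drift = 0.8,
                            noise_sd = 1, n_frames = 60,
                            body_length = 120, frame_rate_hz = 30) {
  turn_direction <- match.arg(turn_direction)
  stopifnot(n_frames >= 2, noise_sd >= 0, body_length > 0)
  structure(as.list(environment()), class = "pose_sim_params")
}

#' Simulate a pose clip of a turning mouse
#'
#' Generates per-frame coordinates of the anchor, nose, and both forepaws
#' while the body axis sweeps through a turn. In the image frame the body
#' rotates; in the body frame the paws sit at `paw_offset` from the axis,
#' which is the recorded ground truth.
#'
#' @param params A [pose_sim_params()].
#' @param seed Optional integer seed.
#' @param anchor Anchor part name (default `"tail_base"`).
#' @return A list: `pose` tibble (`frame`, `part`, `x`, `y`),
#'   `ground_truth` (turn direction and true mean paw offset).
#' @export
simulate_pose_clip <- function(params = pose_sim_params(), seed = NULL,
                               anchor = "tail_base") {
  with_seed(seed, {
    n <- params$n_frames
    # leftward turn = nose swings counterclockwise in the image
    sweep_sign <- if (params$turn_direction == "left") 1 else -1
    angles <- pi / 2 +
      sweep_sign * seq(-params$body_angle_drift / 2,
                       params$body_angle_drift / 2, length.out = n)
    anchor_xy <- c(300, 300)
    rows <- map(seq_len(n), function(f) {
      theta <- angles[f]
      # body-frame axes in image coordinates: +y towards the nose,
      # +x to the animal's right
      fwd <- c(cos(theta), sin(theta))
      right <- c(cos(theta - pi / 2), sin(theta - pi / 2))
      nose <- anchor_xy + params$body_length * fwd
      paw_base <- anchor_xy + 0.45 * params$body_length * fwd
      lp <- paw_base + (params$paw_offset - 12) * right
      rp <- paw_base + (params$paw_offset + 12) * right
      tibble(
        frame = f,
        part = c(anchor, "nose", "left_paw", "right_paw"),
        x = c(anchor_xy[1], nose[1], lp[1], rp[1]) + rnorm(4, 0, params$noise_sd),
        y = c(anchor_xy[2], nose[2], lp[2], rp[2]) + rnorm(4, 0, params$noise_sd)
      )
    })
    list(
      pose = list_rbind(rows),
      ground_truth = tibble(turn_direction = params$turn_direction,
                            paw_offset = params$paw_offset)
    )
  })
}
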