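#' Per-block firing rates of a unit
#'
#' Counts spikes in each `[start, end)` interval (half-open, so a spike on
#' a shared boundary is counted exactly once) and divides by the block
#' duration.
#'
#' @param spike_times Sorted numeric vector of spike times (s).
#' @param blocks A data frame with `start` and `end` columns (s).
#' @return A numeric vector of rates (Hz), one per block.
#' @export
block_rates <- function(spike_times, blocks) {
  stopifnot(is.data.frame(blocks), all(c("start", "end") %in% names(blocks)))
  if (nrow(blocks) == 0) {
    stop_bad_arg("empty block list")
  }
  if (any(blocks$end <= blocks$start)) {
    stop_bad_arg("blocks must have positive duration")
  }
  vapply(seq_len(nrow(blocks)), function(i) {
    n <- sum(spike_times >= blocks$start[i] & spike_times < blocks$end[i])
    n / (blocks$end[i] - blocks$start[i])
  }, numeric(1))
}

#' Laser modulation of a unit's firing
#'
#' Compares firing on laser versus non-laser blocks. Condition mean rates
#' are total spikes over total duration; the modulation index is
#' `(FR_laser - FR_nonlaser) / (FR_laser + FR_nonlaser)`, bounded in
#' \[-1, 1\] (+1 = fires only with laser, -1 = completely silenced).
#' A unit counts as modulated when a two-sided rank-sum test across
#' block-wise rates rejects at `alpha`; its sign (excited/inhibited) then
#' follows the index.
#'
#' @param spike_times Spike times of the unit (s).
#' @param laser_blocks,nonlaser_blocks Block interval tables
#'   (`start`, `end`).
#' @param alpha Block-wise test level (default 0.05).
#' @return A one-row tibble: `fr_laser`, `fr_nonlaser`,
#'   `modulation_index` (NA when both rates are 0), `p`, `modulated`,
#'   `sign`.
#' @export
laser_modulation <- function(spike_times, laser_blocks, nonlaser_blocks,
                             alpha = 0.05) {
  r_l <- block_rates(spike_times, laser_blocks)
  r_nl <- block_rates(spike_times, nonlaser_blocks)
  dur_l <- sum(laser_blocks$end - laser_blocks$start)
  dur_nl <- sum(nonlaser_blocks$end - nonlaser_blocks$start)
  fr_l <- sum(r_l * (laser_blocks$end - laser_blocks$start)) / dur_l
  fr_nl <- sum(r_nl * (nonlaser_blocks$end - nonlaser_blocks$start)) / dur_nl
  idx <- if (fr_l + fr_nl > 0) {
    (fr_l - fr_nl) / (fr_l + fr_nl)
  } else {
    NA_real_
  }
  test <- tryCatch(rank_tests(r_l, r_nl),
                   orientrack_error = function(e) tibble(p = NA_real_,
                                                         z = NA_real_))
  modulated <- !is.na(idx) && !is.na(test$p) && test$p < alpha
  tibble(
    fr_laser = fr_l,
    fr_nonlaser = fr_nl,
    modulation_index = idx,
    p = test$p,
    modulated = modulated,
    sign = dplyr::case_when(
      !modulated ~ "none",
      idx > 0 ~ "excited",
      .default = "inhibited"
    )
  )
}

#' Population summary of laser-modulated units
#'
#' Fraction of units whose firing is significantly modulated by laser
#' stimulation, with counts of excited and inhibited units.
#'
#' @param units A tibble of per-unit [laser_modulation()] rows (a
#'   `unit_id` column is carried through if present).
#' @return A one-row tibble: `n_units`, `n_modulated`,
#'   `fraction_modulated`, `percent_modulated`, `n_excited`,
#'   `n_inhibited`.
#' @export
population_modulation <- function(units) {
  stopifnot(is.data.frame(units), nrow(units) >= 1,
            "modulated" %in% names(units))
  tibble(
    n_units = nrow(units),
    n_modulated = sum(units$modulated),
    fraction_modulated = mean(units$modulated),
    percent_modulated = 100 * mean(units$modulated),
    n_excited = sum(units$sign == "excited"),
    n_inhibited = sum(units$sign == "inhibited")
  )
}

#' Rotate pose coordinates into the body frame
#'
#' Per frame: translates the anchor point (tail base for freely moving
#' clips, headplate center for head-fixed clips) to the origin, computes
#' the angle of the nose relative to the x-axis, and rotates all parts so
#' the nose lies on the +y axis (90 degrees to the anchor). The transform
#' is rigid, so pairwise distances are preserved, and positive x is the
#' animal's right. Frames missing the anchor or nose are skipped.
#'
#' @param pose A tibble with columns `frame`, `part`, `x`, `y`; parts must
#'   include `"nose"` and the anchor plus any paw parts
#'   (`"left_paw"`, `"right_paw"`).
#' @param anchor Name of the anchor part (default `"tail_base"`).
#' @return A tibble of transformed coordinates (`frame`, `part`, `x`, `y`)
#'   with skipped frames recorded in the `dropped_frames` attribute.
#' @export
body_frame_transform <- function(pose, anchor = "tail_base") {
  stopifnot(all(c("frame", "part", "x", "y") %in% names(pose)))
  frames <- split(as_tibble(pose), pose$frame)
  dropped <- integer(0)
  out <- map(frames, function(fr) {
    a <- fr[fr$part == anchor, ]
    nose <- fr[fr$part == "nose", ]
    if (nrow(a) != 1 || nrow(nose) != 1 ||
        anyNA(c(a$x, a$y, nose$x, nose$y))) {
      dropped <<- c(dropped, fr$frame[1])
      return(NULL)
    }
    x <- fr$x - a$x
    y <- fr$y - a$y
    theta <- atan2(nose$y - a$y, nose$x - a$x)
    rot <- pi / 2 - theta  # rotate the nose onto +y
    fr$x <- cos(rot) * x - sin(rot) * y
    fr$y <- sin(rot) * x + cos(rot) * y
    fr
  })
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  attr(res, "dropped_frames") <- dropped
  res
}

#' Mean forepaw lateral position of a clip
#'
#' Averages the body-frame x-positions of both forepaws over all frames of
#' a clip; positive values mean the paws sit to the animal's right of the
#' body axis.
#'
#' @param body_clip Output of [body_frame_transform()].
#' @param paw_parts Part names to average (default both forepaws).
#' @return Mean paw x in the clip (a single number).
#' @export
paw_summary <- function(body_clip, paw_parts = c("left_paw", "right_paw")) {
  paws <- body_clip[body_clip$part %in% paw_parts, ]
  if (nrow(paws) == 0) {
    stop_bad_arg("no valid paw frames in the clip")
  }
  mean(paws$x)
}
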