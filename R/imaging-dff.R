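#' Container for raw soma and neuropil fluorescence traces
#'
#' Pairs each somatic ROI trace with a matched neuropil trace sampled on
#' the same frame clock, plus per-ROI labels (`"labeled"` for projection
#' neurons identified by retrograde tracer, `"unlabeled"`, or `"bouton"`
#' for axonal varicosities).
#'
#' @param soma_raw,neuropil_raw Numeric matrices, ROIs x frames. For
#'   bouton-only sets `neuropil_raw` may be NULL.
#' @param frame_times Frame timestamps in seconds (length = columns).
#' @param roi_labels Character vector per ROI (default `"unlabeled"`).
#' @return A `roi_trace_set`.
#' @export
roi_trace_set <- function(soma_raw, neuropil_raw = NULL, frame_times,
                          roi_labels = NULL) {
  soma_raw <- as.matrix(soma_raw)
  if (!is.null(neuropil_raw)) {
    neuropil_raw <- as.matrix(neuropil_raw)
    stopifnot(all(dim(neuropil_raw) == dim(soma_raw)))
  }
  stopifnot(length(frame_times) == ncol(soma_raw),
            all(diff(frame_times) > 0))
  roi_labels <- roi_labels %||% rep("unlabeled", nrow(soma_raw))
  stopifnot(length(roi_labels) == nrow(soma_raw),
            all(roi_labels %in% c("labeled", "unlabeled", "bouton")))
  structure(
    list(
      soma_raw = soma_raw,
      neuropil_raw = neuropil_raw,
      frame_times = as.numeric(frame_times),
      frame_rate_hz = 1 / median(diff(frame_times)),
      roi_labels = roi_labels
    ),
    class = "roi_trace_set"
  )
}

# Density-mode baseline: location of the maximum of a Gaussian KDE
# (Silverman bandwidth, 512-point grid spanning the 1st-99th percentile).
density_mode <- function(x) {
  if (sd(x) == 0) {
    return(x[1])
  }
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  if (q[1] == q[2]) {
    return(q[1])
  }
  d <- density(x, bw = "nrd0", n = 512, from = q[1], to = q[2])
  d$x[which.max(d$y)]
}

#' Neuropil-corrected percent Delta-F/F
#'
#' Subtracts a scaled neuropil trace from each somatic trace
#' (`F = F_soma - r * F_neuropil`, default `r = 0.7`), estimates the
#' baseline F0 as the fluorescence value of highest density over the
#' session (mode of a kernel-density estimate), and converts to percent:
#' `DFF = (F - F0) / F0 * 100`. ROIs labeled `"bouton"` skip the neuropil
#' subtraction, since bouton traces are not adjusted for contamination.
#' ROIs whose F0 is non-positive are flagged invalid and carry NA traces.
#'
#' @param traces A [roi_trace_set()].
#' @param r Neuropil contamination coefficient (default 0.7).
#' @return A `dff_traces` object: `dff` (ROIs x frames, percent), `f0`,
#'   `valid`, frame metadata, and processing provenance flags.
#' @export
neuropil_dff <- function(traces, r = 0.7) {
  stopifnot(inherits(traces, "roi_trace_set"), r >= 0)
  corrected <- traces$soma_raw
  use_np <- traces$roi_labels != "bouton"
  if (any(use_np)) {
    if (is.null(traces$neuropil_raw)) {
      stop_bad_arg("neuropil traces required for non-bouton ROIs")
    }
    corrected[use_np, ] <- traces$soma_raw[use_np, , drop = FALSE] -
      r * traces$neuropil_raw[use_np, , drop = FALSE]
  }
  f0 <- apply(corrected, 1, density_mode)
  valid <- is.finite(f0) & f0 > 0
  dff <- matrix(NA_real_, nrow(corrected), ncol(corrected))
  if (any(valid)) {
    dff[valid, ] <- 100 * sweep(
      sweep(corrected[valid, , drop = FALSE], 1, f0[valid], "-"),
      1, f0[valid], "/"
    )
  }
  structure(
    list(
      dff = dff,
      f0 = f0,
      valid = valid,
      frame_times = traces$frame_times,
      frame_rate_hz = traces$frame_rate_hz,
      roi_labels = traces$roi_labels,
      neuropil_coefficient = r,
      detrended = FALSE,
      zscored = FALSE
    ),
    class = "dff_traces"
  )
}

# Gaussian smoothing of each row with kernel sd `sigma_s` seconds; edges
# renormalized so the kernel integrates to 1 over the available samples.
gaussian_smooth_rows <- function(mat, frame_rate_hz, sigma_s) {
  sigma_f <- sigma_s * frame_rate_hz
  half <- max(1L, ceiling(4 * sigma_f))
  k <- exp(-((-half:half)^2) / (2 * sigma_f^2))
  t(apply(mat, 1, function(x) {
    num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, length(x)), rep(0, half)),
                         k, sides = 2)
    (num / den)[(half + 1):(half + length(x))]
  }))
}

# Centered running min/max with partial windows at the edges, computed as
# a pmin/pmax reduction over shifted copies (fast for long traces).
roll_extreme <- function(x, width, fn) {
  half <- (width - 1) %/% 2
  n <- length(x)
  pad <- if (identical(fn, min)) Inf else -Inf
  reduce <- if (identical(fn, min)) pmin else pmax
  shifts <- lapply(-half:half, function(s) {
    if (s < 0) {
      c(rep(pad, -s), x[seq_len(n + s)])
    } else if (s > 0) {
      c(x[(s + 1):n], rep(pad, s))
    } else {
      x
    }
  })
  do.call(reduce, shifts)
}

#' Correct slow baseline drift in DFF traces
#'
#' Estimates a moving baseline per ROI by Gaussian smoothing (1 s kernel),
#' minimum filtering, then maximum filtering with a 60 s centered window,
#' and subtracts it from the DFF trace. The min-then-max pair tracks the
#' lower envelope of the trace, following slow drift while ignoring
#' transients shorter than the window. Because the envelope is estimated
#' on the smoothed trace but subtracted from the unsmoothed one, a single
#' pass leaves quiet periods sitting slightly below zero; the estimate is
#' therefore refined by one fixed-point iteration of the same operator,
#' which anchors quiet periods at zero and makes the correction idempotent
#' in practice. Applied before z-scoring.
#'
#' @param dff_obj A `dff_traces` object from [neuropil_dff()].
#' @param gauss_width_s Gaussian kernel sd in seconds (default 1).
#' @param window_s Min/max filter window in seconds (default 60); the
#'   session must be at least this long.
#' @return The `dff_traces` object with drift-corrected `dff` and
#'   `detrended = TRUE`.
#' @export
detrend_baseline <- function(dff_obj, gauss_width_s = 1, window_s = 60) {
  stopifnot(inherits(dff_obj, "dff_traces"))
  dur <- diff(range(dff_obj$frame_times))
  if (dur < window_s) {
    stop_bad_arg("session shorter than the detrending window")
  }
  width <- round(window_s * dff_obj$frame_rate_hz)
  if (width %% 2 == 0) width <- width + 1
  rows <- which(dff_obj$valid)
  envelope <- function(x) {
    sm <- gaussian_smooth_rows(rbind(x), dff_obj$frame_rate_hz,
                               gauss_width_s)[1, ]
    roll_extreme(roll_extreme(sm, width, min), width, max)
  }
  for (i in rows) {
    once <- dff_obj$dff[i, ] - envelope(dff_obj$dff[i, ])
    dff_obj$dff[i, ] <- once - envelope(once)
  }
  dff_obj$detrended <- TRUE
  dff_obj
}

#' z-score DFF traces over the full session
#'
#' Per-ROI standardization of the (typically detrended) session trace to
#' mean 0, SD 1.
#'
#' @param dff_obj A `dff_traces` object.
#' @return The object with standardized `dff` and `zscored = TRUE`.
#' @export
zscore_dff <- function(dff_obj) {
  stopifnot(inherits(dff_obj, "dff_traces"))
  rows <- which(dff_obj$valid)
  for (i in rows) {
    x <- dff_obj$dff[i, ]
    s <- sd(x)
    dff_obj$dff[i, ] <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  dff_obj$zscored <- TRUE
  dff_obj
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("DFF traces: %d ROIs x %d frames at %.1f Hz (%d valid)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate_hz, sum(x$valid)))
  cat(sprintf("  neuropil r = %.2f, detrended = %s, z-scored = %s\n",
              x$neuropil_coefficient, x$detrended, x$zscored))
  invisible(x)
}
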