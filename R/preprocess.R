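## Signal conditioning: zero-phase low-pass filtering of position channels,
## uniform resampling, and similarity alignment of hand landmarks onto the
## body skeleton.

#' Low-pass filter specification
#'
#' Defaults reproduce the pipeline's conditioning stage: a fourth-order
#' Butterworth low-pass with a 12 Hz cut-off, applied forward-backward
#' (zero phase) to every position channel before any angle computation.
#'
#' @param order filter order (default 4).
#' @param cutoff_hz cut-off frequency in Hz (default 12).
#' @param fs sampling rate in Hz; must satisfy `cutoff_hz < fs/2`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 12, fs) {
  if (order < 1) {
    stop_autofma("filter order must be >= 1", class = "autofma_parameter_error")
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop_autofma("fs must be positive", class = "autofma_parameter_error")
  }
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop_autofma("cutoff (%g Hz) must lie in (0, fs/2 = %g Hz)", cutoff_hz, fs / 2,
                 class = "autofma_parameter_error")
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, fs = fs),
            class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering (no phase lag), with odd reflection padding at
#' both ends to suppress edge transients. Zero phase matters here because
#' scoring compares affected and healthy trajectories point by point; a
#' causal filter's lag would inflate the side-to-side deviation.
#'
#' @param x numeric signal (one channel).
#' @param spec a [filter_spec()].
#' @return Filtered signal of the same length.
#' @export
lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n < 3 * spec$order) {
    stop_autofma("signal too short (%d) for stable zero-phase filtering (need >= %d)",
                 n, 3 * spec$order, class = "autofma_length_error")
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$fs / 2), type = "low")
  # generous reflection padding so the filter's startup transient decays
  # before it reaches the signal proper
  pad <- min(n - 1, 15 * (spec$order + 1))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Resample a signal to a fixed length
#'
#' Linear interpolation on a uniform parameterisation of `[0, 1]`;
#' endpoints are preserved. Used to bring unequal-length affected/healthy
#' traces onto a common time base before the deviation feature.
#'
#' @param x numeric signal (length >= 2).
#' @param n target length (>= 2).
#' @return Numeric vector of length `n`.
#' @export
resample_to <- function(x, n) {
  if (n < 2) {
    stop_autofma("resample target length must be >= 2", class = "autofma_parameter_error")
  }
  if (length(x) < 2) {
    stop_autofma("cannot resample a signal with fewer than 2 samples",
                 class = "autofma_length_error")
  }
  if (length(x) == n) return(x)
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n))$y
}

#' Low-pass filter every position channel of a clip
#'
#' @param clip a [motion_clip()].
#' @param spec optional [filter_spec()]; defaults to the clip's sampling
#'   rate with order 4 / 12 Hz.
#' @return The clip with body joints and hand landmarks filtered.
#' @export
filter_clip <- function(clip, spec = NULL) {
  if (is.null(spec)) spec <- filter_spec(fs = clip$fs)
  if (length(clip$body$t) >= 3 * spec$order) {
    clip$body$joints <- lapply(clip$body$joints, function(m) {
      apply(m, 2, lowpass, spec = spec)
    })
  }
  if (!is.null(clip$hand) && length(clip$hand$t) >= 3 * spec$order) {
    lm <- clip$hand$landmarks
    for (k in 1:21) for (d in 1:3) lm[, k, d] <- lowpass(lm[, k, d], spec)
    clip$hand$landmarks <- lm
  }
  clip
}

#' Align hand landmarks onto the body skeleton
#'
#' Applies one similarity transform (translation + uniform scale, no
#' rotation) per frame so that landmark 0 (the hand's wrist origin) maps
#' onto the body wrist joint and landmark 12 (middle fingertip) onto the
#' body hand-tip joint. Because the transform is a similarity, every angle
#' between landmark vectors is preserved, so finger-bend angles are
#' unaffected by alignment.
#'
#' @param hand_lm `21 x 3` matrix of hand landmarks for one frame.
#' @param wrist body wrist position (length-3).
#' @param handtip body hand-tip position (length-3).
#' @return Transformed `21 x 3` landmark matrix.
#' @export
align_hand_to_body <- function(hand_lm, wrist, handtip) {
  stopifnot(nrow(hand_lm) == 21, ncol(hand_lm) == 3)
  v_hand <- hand_lm[13, ] - hand_lm[1, ]          # landmark 0 -> landmark 12
  v_body <- handtip - wrist
  len_hand <- sqrt(sum(v_hand^2))
  len_body <- sqrt(sum(v_body^2))
  if (len_hand < 1e-9 || len_body < 1e-9) {
    stop_autofma("degenerate wrist-to-fingertip segment; cannot align hand",
                 class = "autofma_geometry_error")
  }
  s <- len_body / len_hand
  sweep(sweep(hand_lm, 2, hand_lm[1, ]) * s, 2, wrist, `+`)
}

#' Align every frame of a clip's hand track to its body track
#'
#' Hand and body tracks are brought onto the body time base first (linear
#' resampling of landmarks if the sample counts differ).
#'
#' @param clip a [motion_clip()] with a hand track, canonicalised to the
#'   right limb.
#' @return The clip with `hand$landmarks` aligned to `WRIST_R`/`HANDTIP_R`.
#' @export
align_clip_hand <- function(clip) {
  if (is.null(clip$hand)) return(clip)
  need <- c("WRIST_R", "HANDTIP_R")
  miss <- setdiff(need, names(clip$body$joints))
  if (length(miss)) {
    stop_autofma("hand alignment needs body joints: %s", paste(miss, collapse = ", "),
                 class = "autofma_geometry_error")
  }
  nb <- length(clip$body$t)
  lm <- clip$hand$landmarks
  if (dim(lm)[1] != nb) {
    res <- array(NA_real_, dim = c(nb, 21, 3))
    for (k in 1:21) for (d in 1:3) res[, k, d] <- resample_to(lm[, k, d], nb)
    lm <- res
  }
  for (i in seq_len(nb)) {
    lm[i, , ] <- align_hand_to_body(lm[i, , ],
                                    clip$body$joints$WRIST_R[i, ],
                                    clip$body$joints$HANDTIP_R[i, ])
  }
  clip$hand <- hand_track(clip$body$t, lm)
  clip
}
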