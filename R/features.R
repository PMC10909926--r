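## Per-item feature extraction: ROM / mean velocity / side-to-side
## deviation for angle items, reach-completion ratios for the hand-to-hip
## and finger-nose tasks, and thresholded grip-force totals for the
## pressure-grid items. The healthy limb is always the denominator.

#' Range of motion of an angle trace
#'
#' @param trace numeric angle trace in degrees.
#' @return `max - min`, degrees.
#' @export
rom <- function(trace) {
  if (length(trace) == 0) {
    stop_autofma("cannot compute ROM of an empty trace",
                 class = "autofma_length_error")
  }
  max(trace) - min(trace)
}

#' Mean absolute angular velocity of a trace
#'
#' @param trace numeric angle trace in degrees.
#' @param fs sampling rate in Hz.
#' @return Mean of `|first differences| * fs`, degrees per second.
#' @export
mean_velocity <- function(trace, fs) {
  if (length(trace) < 2) {
    stop_autofma("mean velocity needs at least 2 samples",
                 class = "autofma_length_error")
  }
  mean(abs(diff(trace))) * fs
}

#' Maximum excursion of a trace from its starting value
#'
#' Used as the "maximum bending angle" feature for the mass flexion and
#' mass extension items: the largest deviation from the initial posture,
#' which equals the peak bend for a flexion that starts extended and the
#' peak extension excursion for a motion that starts flexed.
#'
#' @param trace numeric angle trace in degrees.
#' @return Maximum of `|trace - trace[1]|`, degrees.
#' @export
max_excursion <- function(trace) {
  if (length(trace) == 0) {
    stop_autofma("cannot compute excursion of an empty trace",
                 class = "autofma_length_error")
  }
  max(abs(trace - trace[1]))
}

#' Side-to-side deviation (RMS) between two traces
#'
#' Both traces are resampled to a common length `n` on a uniform
#' parameterisation, and the deviation is
#' `sqrt(sum(dd_i^2) / n)` with `dd` the pointwise affected-healthy
#' difference - a root-mean-square distance, hence the triangle inequality
#' holds.
#'
#' @param affected,healthy numeric angle traces in degrees.
#' @param n common resampling length (defaults to the longer trace).
#' @return Deviation in degrees.
#' @export
deviation_sd <- function(affected, healthy, n = max(length(affected), length(healthy))) {
  a <- resample_to(affected, n)
  h <- resample_to(healthy, n)
  sqrt(sum((a - h)^2) / n)
}

hip_centre <- function(clip, i) {
  (joint_at(clip, "HIP_L", i) + joint_at(clip, "HIP_R", i)) / 2
}

#' Hand-to-hip motion length ratio
#'
#' Minimum over time of the hand-to-hip-centre distance divided by that
#' distance at the first sample. 0 means the hip was reached, 1 means the
#' hand never approached it.
#'
#' @param clip a prepared [motion_clip()] (right limb).
#' @param hand_joint body joint used as the hand position (default
#'   `"WRIST_R"`).
#' @return List with `alpha` (the ratio) and `completion = 1 - alpha`.
#' @export
hand_hip_ratio <- function(clip, hand_joint = "WRIST_R") {
  n <- length(clip$body$t)
  d <- vapply(seq_len(n), function(i) {
    vnorm(joint_at(clip, hand_joint, i) - hip_centre(clip, i))
  }, numeric(1))
  if (d[1] < 1e-6) {
    stop_autofma("degenerate start: hand already at the hip centre",
                 class = "autofma_degenerate_start_error")
  }
  alpha <- min(d) / d[1]
  list(alpha = alpha, completion = 1 - alpha)
}

#' Finger-nose reach features
#'
#' Computes, from the fingertip trajectory of a finger-nose clip:
#' the vertical fingertip-nose distance ratio `gamma` (and its completion
#' `1 - min gamma`), the left/right shoulder horizontal-distance ratio
#' `beta` at closest approach, the maximum fingertip speed, the mean
#' fingertip speed, the mean acceleration magnitude, and the movement time
#' from onset (speed above 5% of the maximum) to closest approach.
#' The fingertip is hand landmark 8 (index tip) when a hand track is
#' present, otherwise the body `HANDTIP_R` joint.
#'
#' If the fingertip's total displacement stays below `min_move` the task
#' was not performed (failure to initiate): the speed and acceleration
#' features are reported as zero rather than as tracker-noise derivatives.
#'
#' @param clip a prepared [motion_clip()] (right limb) of the finger-nose
#'   task.
#' @param onset_frac onset threshold as a fraction of the peak speed.
#' @param min_move movement-detection floor in metres: below this maximum
#'   fingertip displacement the motion counts as not initiated.
#' @return List of reach features (`gamma_min`, `completion`, `beta`,
#'   `vmax`, `mv`, `ma`, `move_time`, `displacement`).
#' @export
finger_nose_features <- function(clip, onset_frac = 0.05, min_move = 0.02) {
  n <- length(clip$body$t)
  tip <- if (!is.null(clip$hand)) {
    clip$hand$landmarks[, 9, ]                 # landmark 8 = index fingertip
  } else {
    clip$body$joints$HANDTIP_R
  }
  if (is.null(tip)) {
    stop_autofma("finger-nose clip has neither hand landmarks nor HANDTIP_R",
                 class = "autofma_missing_joint_error")
  }
  nose <- clip$body$joints$NOSE
  if (is.null(nose)) {
    stop_autofma("finger-nose clip lacks the NOSE joint",
                 class = "autofma_missing_joint_error")
  }
  dz <- abs(tip[, 2] - nose[, 2])              # vertical fingertip-nose distance
  if (dz[1] < 1e-6) {
    stop_autofma("degenerate start: fingertip already at nose height",
                 class = "autofma_degenerate_start_error")
  }
  gam <- dz / dz[1]
  i_close <- which.min(dz)
  sl <- joint_at(clip, "SHOULDER_L", i_close)
  sr <- joint_at(clip, "SHOULDER_R", i_close)
  horiz <- function(p, q) sqrt((p[1] - q[1])^2 + (p[3] - q[3])^2)
  dl <- horiz(tip[i_close, ], sl)
  dr <- horiz(tip[i_close, ], sr)
  if (dr < 1e-6) dr <- 1e-6
  fs <- clip$fs
  displacement <- max(sqrt(rowSums(sweep(tip, 2, tip[1, ])^2)))
  if (displacement < min_move) {
    vmax <- 0; mv <- 0; ma <- 0; move_time <- 0
  } else {
    vel <- diff(tip) * fs                      # (n-1) x 3 velocity vectors
    speed <- sqrt(rowSums(vel^2))
    vmax <- max(speed)
    acc <- diff(vel) * fs
    ma <- mean(sqrt(rowSums(acc^2)))
    onset <- which(speed > onset_frac * vmax)[1]
    move_time <- if (is.na(onset) || vmax == 0) 0 else {
      max(0, clip$body$t[i_close] - clip$body$t[onset])
    }
    mv <- mean(speed)
  }
  list(gamma_min = min(gam), completion = 1 - min(gam), beta = dl / dr,
       vmax = vmax, mv = mv, ma = ma, move_time = move_time,
       displacement = displacement)
}

#' Total effective grip force from a frame sequence
#'
#' Takes the per-cell maximum over time, zeroes cells below the effective
#' gripping threshold, and sums the surviving cells.
#'
#' @param frames list of [force_frame()] objects (same motion/side).
#' @param threshold effective-grip threshold in newtons (default 0.1 N,
#'   the minimum force resolved by the pressure grid).
#' @return List with `total_force` (N), `threshold`, and `max_grid`
#'   (16 x 16 per-cell maxima after thresholding).
#' @export
grip_force_total <- function(frames, threshold = 0.1) {
  if (length(frames) == 0) {
    stop_autofma("no force frames supplied", class = "autofma_length_error")
  }
  if (threshold < 0) {
    stop_autofma("grip threshold must be >= 0", class = "autofma_parameter_error")
  }
  g <- Reduce(pmax, lapply(frames, `[[`, "grid"))
  g[g < threshold] <- 0
  list(total_force = sum(g), threshold = threshold, max_grid = g)
}

#' Mirror a force frame left-right
#'
#' Reverses the grid columns so a healthy-hand print can be compared
#' cell-by-cell with the contralateral affected hand.
#'
#' @param frame a [force_frame()].
#' @return The mirrored frame.
#' @export
mirror_force <- function(frame) {
  frame$grid <- frame$grid[, 16:1]
  frame
}

#' Pipeline configuration
#'
#' @param grip_threshold effective-grip threshold in newtons.
#' @param hand_joint body joint used for the hand-to-hip task.
#' @param onset_frac movement-onset threshold (fraction of peak speed).
#' @param min_move movement-detection floor for the finger-nose task (m).
#' @param sd_clip upper clip for the normalised deviation input.
#' @param filter optional [filter_spec()] override (default: order 4,
#'   12 Hz at each clip's own sampling rate).
#' @param rescale66 rescale the 30-item total to the 66-point clinical
#'   scale before severity classification.
#' @return An `assess_config` list.
#' @export
assess_config <- function(grip_threshold = 0.1, hand_joint = "WRIST_R",
                          onset_frac = 0.05, min_move = 0.02, sd_clip = 1.4,
                          filter = NULL, rescale66 = FALSE) {
  structure(list(grip_threshold = grip_threshold, hand_joint = hand_joint,
                 onset_frac = onset_frac, min_move = min_move,
                 sd_clip = sd_clip, filter = filter,
                 rescale66 = rescale66),
            class = "assess_config")
}

ratio_to_healthy <- function(a, h, what, eps = 1e-9) {
  if (!is.finite(h) || h <= eps) {
    stop_autofma("uninformative healthy reference for %s (healthy value %s)",
                 what, format(h), class = "autofma_uninformative_reference_error")
  }
  a / h
}

## Symmetric "distance from parity" transform: ratio 1 -> 1, deviation in
## either direction decreases the value linearly, floor at 0.
parity_closeness <- function(ratio) max(0, 1 - abs(ratio - 1))

prepare_clip <- function(rec, motion, side, config, needs_hand, cache) {
  key <- paste(motion, side, needs_hand, sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  cl <- get_clip(rec, motion, side)
  cl <- filter_clip(cl, config$filter)
  if (needs_hand && !is.null(cl$hand)) cl <- align_clip_hand(cl)
  cache[[key]] <- cl
  cl
}

angle_sub_features <- function(rec, motion, label, config, cache) {
  ca <- prepare_clip(rec, motion, "affected", config,
                     label %in% c("forearm_pronation", "wrist_flexion",
                                  "finger_bend_thumb", "finger_bend_four_mean"),
                     cache)
  ch <- prepare_clip(rec, motion, "healthy", config,
                     label %in% c("forearm_pronation", "wrist_flexion",
                                  "finger_bend_thumb", "finger_bend_four_mean"),
                     cache)
  ta <- angle_traces(ca, label)$traces[[label]]
  th <- angle_traces(ch, label)$traces[[label]]
  hrom <- rom(th)
  rom_ratio <- ratio_to_healthy(rom(ta), hrom, sprintf("%s ROM (%s)", label, motion))
  mv_ratio <- ratio_to_healthy(mean_velocity(ta, ca$fs), mean_velocity(th, ch$fs),
                               sprintf("%s MV (%s)", label, motion))
  delta <- deviation_sd(ta, th)
  sd_norm <- min(delta / hrom, config$sd_clip)
  list(inputs = c(rom_ratio = rom_ratio, mv_ratio = mv_ratio, sd = sd_norm),
       audit = list(motion = motion, label = label,
                    arom = rom(ta), hrom = hrom,
                    amv = mean_velocity(ta, ca$fs), hmv = mean_velocity(th, ch$fs),
                    delta = delta))
}

finger_sub_features <- function(rec, motion, part, config, cache) {
  label <- if (part == "thumb") "finger_bend_thumb" else "finger_bend_four_mean"
  ca <- prepare_clip(rec, motion, "affected", config, TRUE, cache)
  ch <- prepare_clip(rec, motion, "healthy", config, TRUE, cache)
  ta <- angle_traces(ca, label)$traces[[label]]
  th <- angle_traces(ch, label)$traces[[label]]
  angle_ratio <- ratio_to_healthy(max_excursion(ta), max_excursion(th),
                                  sprintf("%s max bend (%s)", part, motion))
  mv_ratio <- ratio_to_healthy(mean_velocity(ta, ca$fs), mean_velocity(th, ch$fs),
                               sprintf("%s bend MV (%s)", part, motion))
  list(inputs = c(angle_ratio = angle_ratio, mv_ratio = mv_ratio),
       audit = list(motion = motion, part = part,
                    a_angle = max_excursion(ta), h_angle = max_excursion(th)))
}

#' Compute the fuzzy-inference inputs for one item
#'
#' Resolves the item's recipe (angle ratios, reach completion, grip-force
#' ratio, or finger-nose coordination ratios) against both sides of a
#' recording. Every ratio uses the healthy side as denominator; a healthy
#' reference of zero raises an "uninformative healthy reference" error
#' naming the feature.
#'
#' @param rec a canonicalised [fma_recording()].
#' @param item one item of [build_registry()].
#' @param config an [assess_config()].
#' @return List with one element per sub-motion, each containing `inputs`
#'   (named vector for the FIS) and `audit` (raw feature values).
#' @export
item_features <- function(rec, item, config = assess_config()) {
  rec <- canonicalise_recording(rec)
  cache <- new.env(parent = emptyenv())
  switch(item$kind,
    angle = lapply(item$subs, function(sb) {
      angle_sub_features(rec, sb$motion, sb$label, config, cache)
    }),
    finger = lapply(item$subs, function(sb) {
      finger_sub_features(rec, sb$motion, sb$part, config, cache)
    }),
    alpha = {
      ca <- prepare_clip(rec, item$subs[[1]]$motion, "affected", config, FALSE, cache)
      ch <- prepare_clip(rec, item$subs[[1]]$motion, "healthy", config, FALSE, cache)
      ra <- hand_hip_ratio(ca, config$hand_joint)
      rh <- hand_hip_ratio(ch, config$hand_joint)
      ratio <- ratio_to_healthy(ra$completion, rh$completion,
                                "hand-to-hip reach completion")
      list(list(inputs = c(reach_ratio = ratio),
                audit = list(alpha_affected = ra$alpha, alpha_healthy = rh$alpha)))
    },
    force = {
      m <- item$subs[[1]]$motion
      fa <- grip_force_total(get_force_frames(rec, m, "affected"),
                             config$grip_threshold)
      fh <- grip_force_total(get_force_frames(rec, m, "healthy"),
                             config$grip_threshold)
      ratio <- ratio_to_healthy(fa$total_force, fh$total_force,
                                sprintf("grip force sum (%s)", m))
      list(list(inputs = c(force_ratio = ratio),
                audit = list(a_fsum = fa$total_force, h_fsum = fh$total_force,
                             threshold = fa$threshold)))
    },
    tremor = ,
    dysmetria = ,
    speed = {
      m <- item$subs[[1]]$motion
      ca <- prepare_clip(rec, m, "affected", config, FALSE, cache)
      ch <- prepare_clip(rec, m, "healthy", config, FALSE, cache)
      fa <- finger_nose_features(ca, config$onset_frac, config$min_move)
      fh <- finger_nose_features(ch, config$onset_frac, config$min_move)
      inputs <- switch(item$kind,
        tremor = c(
          mv_ratio = ratio_to_healthy(fa$mv, fh$mv, "fingertip MV"),
          ma_sym = parity_closeness(
            ratio_to_healthy(fa$ma, fh$ma, "fingertip mean acceleration"))),
        dysmetria = c(
          beta_sym = parity_closeness(
            ratio_to_healthy(fa$beta, fh$beta, "shoulder-distance ratio beta")),
          gamma_ratio = ratio_to_healthy(fa$completion, fh$completion,
                                         "vertical reach completion")),
        speed = c(
          vmax_ratio = ratio_to_healthy(fa$vmax, fh$vmax, "peak fingertip speed"))
      )
      list(list(inputs = inputs, audit = list(affected = fa, healthy = fh)))
    },
    stop_autofma("unknown item kind: %s", item$kind, class = "autofma_config_error")
  )
}
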