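## Domain types: clips, force frames, recordings, and their validators.
## Canonical joint vocabulary is the Azure-Kinect-style body skeleton.

#' Canonical body-joint names
#'
#' The joint vocabulary accepted in recordings. Positions are metres in a
#' right-handed camera frame (x anterior, y up, z to the subject's right
#' after canonicalisation).
#'
#' @export
BODY_JOINTS <- c(
  "PELVIS", "SPINE_CHEST", "NECK", "NOSE",
  "SHOULDER_L", "SHOULDER_R", "ELBOW_L", "ELBOW_R",
  "WRIST_L", "WRIST_R", "HANDTIP_L", "HANDTIP_R",
  "HIP_L", "HIP_R"
)

#' Motion codes of the assessment protocol
#' @export
MOTION_IDS <- paste0("M", 1:21)

#' Grasp motions measured with the 16x16 pressure grid
#' @export
FORCE_MOTIONS <- paste0("M", 16:20)

#' Pressure-grid geometry: 16x16 sensing units over 150 mm x 150 mm
#' @export
FORCE_GRID_DIM <- c(16L, 16L)

#' Cell pitch of the pressure grid in metres (7.5 mm square units)
#' @export
FORCE_CELL_PITCH <- 0.0075

stop_autofma <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "autofma_error")))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

check_time <- function(t, what) {
  if (!is_finite_num(t) || any(t < 0)) {
    stop_autofma("%s: time stamps must be finite and non-negative", what,
                 class = "autofma_validation_error")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop_autofma("%s: time stamps must be strictly increasing", what,
                 class = "autofma_validation_error")
  }
  invisible(t)
}

#' Construct a body-trajectory block
#'
#' @param t numeric vector of time stamps in seconds, strictly increasing.
#' @param joints named list mapping joint name to an `n x 3` matrix of
#'   positions in metres (one row per sample in `t`).
#' @return A validated `body_track` list.
#' @export
body_track <- function(t, joints) {
  check_time(t, "body track")
  if (is.null(names(joints)) || any(!nzchar(names(joints)))) {
    stop_autofma("body track: joints must be a named list",
                 class = "autofma_validation_error")
  }
  unknown <- setdiff(names(joints), BODY_JOINTS)
  if (length(unknown)) {
    stop_autofma("body track: unknown joint name(s): %s",
                 paste(unknown, collapse = ", "),
                 class = "autofma_validation_error")
  }
  joints <- lapply(joints, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (j in names(joints)) {
    m <- joints[[j]]
    if (nrow(m) != length(t) || ncol(m) != 3) {
      stop_autofma("body track: joint %s must be a %d x 3 matrix", j, length(t),
                   class = "autofma_validation_error")
    }
    if (!all(is.finite(m))) {
      stop_autofma("body track: joint %s has non-finite coordinates", j,
                   class = "autofma_validation_error")
    }
  }
  structure(list(t = as.numeric(t), joints = joints), class = "body_track")
}

#' Construct a hand-landmark trajectory block
#'
#' @param t numeric vector of time stamps in seconds.
#' @param landmarks numeric array of dimension `n x 21 x 3`: the 21 hand
#'   key points (index 1 = landmark 0, the wrist origin) in metres.
#' @return A validated `hand_track` list.
#' @export
hand_track <- function(t, landmarks) {
  check_time(t, "hand track")
  landmarks <- array(as.numeric(landmarks), dim = dim(landmarks))
  d <- dim(landmarks)
  if (length(d) != 3 || d[1] != length(t) || d[2] != 21 || d[3] != 3) {
    stop_autofma("hand track: landmarks must be an n x 21 x 3 array (21 key points)",
                 class = "autofma_validation_error")
  }
  if (!all(is.finite(landmarks))) {
    stop_autofma("hand track: non-finite landmark coordinates",
                 class = "autofma_validation_error")
  }
  structure(list(t = as.numeric(t), landmarks = landmarks), class = "hand_track")
}

#' Construct a motion clip
#'
#' A clip is one recorded sub-motion (M1--M21) for one limb.
#'
#' @param motion_id one of `MOTION_IDS`.
#' @param side `"affected"` or `"healthy"`.
#' @param fs sampling rate in Hz; must exceed 24 Hz so that the 12 Hz
#'   low-pass stage is below Nyquist.
#' @param body a [body_track()].
#' @param hand optionally a [hand_track()] (required only for wrist,
#'   forearm-rotation and finger items).
#' @return A `motion_clip` object.
#' @export
motion_clip <- function(motion_id, side, fs, body, hand = NULL) {
  if (!motion_id %in% MOTION_IDS) {
    stop_autofma("unknown motion id: %s", motion_id,
                 class = "autofma_validation_error")
  }
  side <- match.arg(side, c("affected", "healthy"))
  if (!is_finite_num(fs) || length(fs) != 1 || fs <= 24) {
    stop_autofma("clip %s/%s: fs must be a single value > 24 Hz", motion_id, side,
                 class = "autofma_validation_error")
  }
  if (!inherits(body, "body_track") || length(body$t) == 0) {
    stop_autofma("clip %s/%s: body must be a non-empty body_track", motion_id, side,
                 class = "autofma_validation_error")
  }
  if (!is.null(hand) && !inherits(hand, "hand_track")) {
    stop_autofma("clip %s/%s: hand must be a hand_track or NULL", motion_id, side,
                 class = "autofma_validation_error")
  }
  structure(list(motion_id = motion_id, side = side, fs = fs,
                 body = body, hand = hand),
            class = "motion_clip")
}

#' Construct a pressure-grid force frame
#'
#' @param t time stamp in seconds.
#' @param grid 16x16 numeric matrix of cell forces in newtons (row-major
#'   flat vectors of length 256 are accepted).
#' @param motion_id one of `FORCE_MOTIONS` (M16--M20).
#' @param side `"affected"` or `"healthy"`.
#' @return A `force_frame` object.
#' @export
force_frame <- function(t, grid, motion_id, side) {
  if (!motion_id %in% FORCE_MOTIONS) {
    stop_autofma("force frame: motion must be one of %s",
                 paste(FORCE_MOTIONS, collapse = ", "),
                 class = "autofma_validation_error")
  }
  side <- match.arg(side, c("affected", "healthy"))
  if (is.matrix(grid)) {
    if (!all(dim(grid) == FORCE_GRID_DIM)) {
      stop_autofma("force frame: grid must be 16 x 16 (got %d x %d)",
                   nrow(grid), ncol(grid), class = "autofma_dimension_error")
    }
  } else {
    if (length(grid) != 256) {
      stop_autofma("force frame: expected 256 cell values, got %d", length(grid),
                   class = "autofma_dimension_error")
    }
    grid <- matrix(as.numeric(grid), nrow = 16, ncol = 16, byrow = TRUE)
  }
  storage.mode(grid) <- "double"
  if (!all(is.finite(grid))) {
    stop_autofma("force frame: non-finite force values",
                 class = "autofma_validation_error")
  }
  if (any(grid < 0)) {
    stop_autofma("force frame: negative force values",
                 class = "autofma_validation_error")
  }
  if (!is_finite_num(t) || length(t) != 1 || t < 0) {
    stop_autofma("force frame: t must be a single non-negative number",
                 class = "autofma_validation_error")
  }
  structure(list(t = as.numeric(t), grid = grid,
                 motion_id = motion_id, side = side),
            class = "force_frame")
}

#' Construct a recording
#'
#' The container for a full assessment session: every clip and force frame
#' for both the affected and the healthy limb.
#'
#' @param subject_id free-text subject identifier.
#' @param affected_side `"left"` or `"right"` (the hemiplegic side).
#' @param clips list of [motion_clip()] objects.
#' @param force_frames list of [force_frame()] objects.
#' @param check_pairing require that every motion recorded on one side is
#'   also present on the other side.
#' @return A `fma_recording` object.
#' @export
fma_recording <- function(subject_id, affected_side, clips,
                          force_frames = list(), check_pairing = TRUE) {
  affected_side <- match.arg(affected_side, c("left", "right"))
  stopifnot(all(vapply(clips, inherits, logical(1), "motion_clip")))
  stopifnot(all(vapply(force_frames, inherits, logical(1), "force_frame")))
  rec <- structure(list(subject_id = as.character(subject_id),
                        affected_side = affected_side,
                        clips = clips, force_frames = force_frames,
                        canonical = FALSE),
                   class = "fma_recording")
  if (check_pairing) check_paired_sides(rec)
  rec
}

check_paired_sides <- function(rec) {
  key <- function(objs) {
    data.frame(motion = vapply(objs, `[[`, "", "motion_id"),
               side = vapply(objs, `[[`, "", "side"))
  }
  for (blk in list(key(rec$clips), key(rec$force_frames))) {
    if (!nrow(blk)) next
    for (m in unique(blk$motion)) {
      sides <- unique(blk$side[blk$motion == m])
      if (length(sides) == 1) {
        stop_autofma("unpaired side: motion %s has only the %s side", m, sides,
                     class = "autofma_unpaired_side_error")
      }
    }
  }
  invisible(rec)
}

#' Retrieve one clip from a recording
#'
#' @param rec a [fma_recording()].
#' @param motion_id motion code.
#' @param side `"affected"` or `"healthy"`.
#' @return The matching `motion_clip`, or an error if absent.
#' @export
get_clip <- function(rec, motion_id, side) {
  for (cl in rec$clips) {
    if (cl$motion_id == motion_id && cl$side == side) return(cl)
  }
  stop_autofma("recording has no %s-side clip for motion %s", side, motion_id,
               class = "autofma_missing_clip_error")
}

#' Retrieve the force frames of one grasp motion
#'
#' @inheritParams get_clip
#' @return List of `force_frame` objects (possibly empty).
#' @export
get_force_frames <- function(rec, motion_id, side) {
  Filter(function(f) f$motion_id == motion_id && f$side == side,
         rec$force_frames)
}

mirror_points <- function(m) {
  m[, 3] <- -m[, 3]
  m
}

swap_lr <- function(nm) {
  out <- nm
  out[grepl("_L$", nm)] <- sub("_L$", "_R", nm[grepl("_L$", nm)])
  out[grepl("_R$", nm)] <- sub("_R$", "_L", nm[grepl("_R$", nm)])
  out
}

mirror_clip <- function(cl) {
  cl$body$joints <- lapply(cl$body$joints, mirror_points)
  names(cl$body$joints) <- swap_lr(names(cl$body$joints))
  if (!is.null(cl$hand)) {
    cl$hand$landmarks[, , 3] <- -cl$hand$landmarks[, , 3]
  }
  cl$mirrored <- !isTRUE(cl$mirrored)
  cl
}

#' Canonicalise a recording to right-limb geometry
#'
#' Left-limb clips are reflected through the sagittal plane (z -> -z, with
#' left/right joint names swapped) so that all downstream kinematics is
#' written once for the right side. Reflecting a left hand yields a valid
#' right hand, so palm-normal conventions are preserved.
#'
#' @param rec a [fma_recording()].
#' @return The recording with every clip expressed as a right limb and
#'   `rec$canonical = TRUE`.
#' @export
canonicalise_recording <- function(rec) {
  if (isTRUE(rec$canonical)) return(rec)
  rec$clips <- lapply(rec$clips, function(cl) {
    left_limb <- (cl$side == "affected") == (rec$affected_side == "left")
    if (left_limb) mirror_clip(cl) else cl
  })
  rec$canonical <- TRUE
  rec
}

#' @export
print.fma_recording <- function(x, ...) {
  cat(sprintf("<fma_recording> subject %s, affected side: %s\n",
              x$subject_id, x$affected_side))
  cat(sprintf("  %d clips (%d motions), %d force frames%s\n",
              length(x$clips),
              length(unique(vapply(x$clips, `[[`, "", "motion_id"))),
              length(x$force_frames),
              if (isTRUE(x$canonical)) ", canonicalised" else ""))
  invisible(x)
}
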