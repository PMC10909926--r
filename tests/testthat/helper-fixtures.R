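# Small hand-built fixtures used across test files. Everything is generated
# in code; no binary data.

# A minimal standing skeleton sample (single frame) with an axis-aligned
# trunk: x anterior, y up, z to the subject's right.
basic_joints <- function() {
  list(
    PELVIS      = c(0, 0, 0),
    HIP_L       = c(0, -0.05, -0.09),
    HIP_R       = c(0, -0.05, 0.09),
    SPINE_CHEST = c(0, 0.35, 0),
    NECK        = c(0, 0.55, 0),
    NOSE        = c(0.10, 0.70, 0),
    SHOULDER_L  = c(0, 0.50, -0.18),
    SHOULDER_R  = c(0, 0.50, 0.18),
    ELBOW_R     = c(0, 0.22, 0.20),
    WRIST_R     = c(0, -0.03, 0.20),
    HANDTIP_R   = c(0, -0.11, 0.20)
  )
}

# Build a motion clip from a list of per-frame joint lists.
clip_from_frames <- function(frames, motion_id = "M1", side = "affected",
                             fs = 30) {
  t <- (seq_along(frames) - 1) / fs
  nms <- names(frames[[1]])
  joints <- lapply(nms, function(j) {
    do.call(rbind, lapply(frames, `[[`, j))
  })
  names(joints) <- nms
  motion_clip(motion_id, side, fs, body_track(t, joints))
}

# Static clip repeating one joint sample n times.
static_clip <- function(joints = basic_joints(), n = 30, ...) {
  clip_from_frames(rep(list(joints), n), ...)
}

# A tiny paired recording (one motion both sides) for I/O tests.
tiny_recording <- function() {
  a <- static_clip(side = "affected")
  h <- static_clip(side = "healthy")
  fr <- list(force_frame(0.1, matrix(1, 16, 16), "M19", "affected"),
             force_frame(0.1, matrix(2, 16, 16), "M19", "healthy"))
  fma_recording("T1", "right", list(a, h), fr)
}

# Apply a rigid transform (rotation matrix R, translation v) to a clip.
transform_clip <- function(clip, R, v) {
  clip$body$joints <- lapply(clip$body$joints, function(m) {
    sweep(m %*% t(R), 2, v, `+`)
  })
  if (!is.null(clip$hand)) {
    lm <- clip$hand$landmarks
    for (i in seq_len(dim(lm)[1])) {
      lm[i, , ] <- sweep(lm[i, , ] %*% t(R), 2, v, `+`)
    }
    clip$hand$landmarks <- lm
  }
  clip
}

# A plausibly bent hand-landmark matrix (the generator's template).
hand_template_like <- function(bend = 30) autofma:::hand_template(bend)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y+w*z),   2*(x*z-w*y),
           2*(x*y-w*z),     1 - 2*(x^2+z^2), 2*(y*z+w*x),
           2*(x*z+w*y),     2*(y*z-w*x),   1 - 2*(x^2+y^2)), 3, 3)
}
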