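## Synthetic paired healthy/affected recordings with known, controllable
## impairment. Healthy motion uses minimum-jerk angle profiles on a posed
## seated skeleton (fixed segment lengths); the affected side is derived by
## scaling excursions, slowing the movement phase, adding a 6 Hz tremor
## sinusoid and Gaussian position jitter. Everything is deterministic for a
## given seed. These are stand-ins for patient kinematics, not claims about
## pathological synergy patterns.

#' Impairment profile for the synthetic generator
#'
#' @param rom_scale multiplies every affected-side excursion (angle ranges,
#'   reach displacements, shoulder offsets); 1 = unimpaired.
#' @param velocity_scale slows the affected movement phase (the motion
#'   takes `1/velocity_scale` times longer); 1 = unimpaired. Values below
#'   ~0.2 truncate the motion within the clip.
#' @param tremor_amplitude degrees of 6 Hz sinusoidal tremor added to the
#'   affected side's animated joint angles (and, scaled to metres, to the
#'   finger-nose fingertip).
#' @param force_scale multiplies the affected hand's pressure-grid blobs.
#' @param disabled_fingers subset of
#'   `c("thumb", "index", "middle", "ring", "little")` whose force blobs
#'   are absent on the affected side.
#' @param noise_sd standard deviation (metres) of band-limited (1 Hz
#'   low-passed) Gaussian position jitter added to every joint and landmark
#'   on both sides - the slowly wandering error mode of model-based
#'   markerless trackers after their own temporal smoothing.
#' @param seed integer RNG seed; identical profiles yield identical
#'   recordings.
#' @param fs sampling rate in Hz.
#' @param clip_s clip length per sub-motion in seconds.
#' @param move_s duration of the movement phase (before the hold) for
#'   non-cyclic motions, seconds.
#' @return An `impairment_profile` list.
#' @export
impairment_profile <- function(rom_scale = 1, velocity_scale = 1,
                               tremor_amplitude = 0, force_scale = 1,
                               disabled_fingers = character(),
                               noise_sd = 5e-5, seed = 1L,
                               fs = 30, clip_s = 5, move_s = 1) {
  for (v in c(rom_scale, velocity_scale, force_scale)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop_autofma("impairment scales must lie in [0, 1]",
                   class = "autofma_parameter_error")
    }
  }
  if (tremor_amplitude < 0 || noise_sd < 0) {
    stop_autofma("tremor amplitude and noise sd must be >= 0",
                 class = "autofma_parameter_error")
  }
  fingers <- c("thumb", "index", "middle", "ring", "little")
  if (length(setdiff(disabled_fingers, fingers))) {
    stop_autofma("disabled_fingers must be a subset of %s",
                 paste(fingers, collapse = ", "),
                 class = "autofma_parameter_error")
  }
  structure(list(rom_scale = rom_scale, velocity_scale = velocity_scale,
                 tremor_amplitude = tremor_amplitude, force_scale = force_scale,
                 disabled_fingers = disabled_fingers, noise_sd = noise_sd,
                 seed = as.integer(seed), fs = fs, clip_s = clip_s,
                 move_s = move_s),
            class = "impairment_profile")
}

#' Impairment profile targeting a uniform item score
#'
#' Returns a profile whose feature ratios land on the plateau (core) of the
#' low, medium or high membership functions, so that every item scores
#' `level` by construction: impairment scales 0, 0.5 and 1 for levels 0, 1
#' and 2 respectively, no tremor.
#'
#' @param level target item score (0, 1 or 2).
#' @param seed RNG seed.
#' @return An [impairment_profile()].
#' @export
score_target_profile <- function(level, seed = 1L) {
  if (!level %in% 0:2) {
    stop_autofma("level must be 0, 1 or 2", class = "autofma_parameter_error")
  }
  s <- c(0, 0.5, 1)[level + 1]
  impairment_profile(rom_scale = s, velocity_scale = 1, tremor_amplitude = 0,
                     force_scale = s, seed = seed)
}

## ---- skeleton and forward kinematics -------------------------------------

SEG_UPPER_ARM <- 0.28
SEG_FOREARM <- 0.25

static_skeleton <- function() {
  list(
    PELVIS      = c(0, 0, 0),
    HIP_L       = c(0, -0.05, -0.09),
    HIP_R       = c(0, -0.05, 0.09),
    SPINE_CHEST = c(0, 0.35, 0),
    NECK        = c(0, 0.55, 0),
    NOSE        = c(0.10, 0.70, 0),
    SHOULDER_L  = c(0, 0.50, -0.18),
    SHOULDER_R  = c(0, 0.50, 0.18),
    ELBOW_L     = c(0, 0.22, -0.20),
    WRIST_L     = c(0, -0.04, -0.20),
    HANDTIP_L   = c(0, -0.12, -0.20)
  )
}

rot_axis <- function(k, th) {
  # Rodrigues rotation matrix about unit axis k
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Pose parameters (degrees):
## a = plane of elevation, b = elevation, c = axial rotation,
## e = elbow flexion, p = forearm rotation, w = wrist flexion,
## bend = finger curl, sh_elev / sh_ret = scapular elevation and
## retraction angles (the shoulder rides on a neck-centred sphere, so the
## commanded angles scale linearly in the measured shoulder-neck angles).
arm_joints <- function(pose) {
  sk <- static_skeleton()
  v0 <- sk$SHOULDER_R - sk$NECK
  r0 <- vnorm(v0)
  dir <- rot_x(-rad(pose$sh_elev)) %*% rot_y(-rad(pose$sh_ret)) %*% (v0 / r0)
  SR <- sk$NECK + r0 * as.numeric(dir)
  R <- rot_y(rad(pose$a)) %*% rot_x(-rad(pose$b)) %*% rot_y(rad(pose$c))
  E <- SR + SEG_UPPER_ARM * as.numeric(R %*% c(0, -1, 0))
  e_r <- rad(pose$e)
  d_local <- c(sin(e_r), -cos(e_r), 0)
  W <- E + SEG_FOREARM * as.numeric(R %*% d_local)
  sk$SHOULDER_R <- SR
  sk$ELBOW_R <- E
  sk$WRIST_R <- W
  sk$arm_R <- R
  sk
}

## Hand basis at the wrist: pronation p about the forearm axis relative to
## the elbow flexion-plane normal, then dorsiflexion w about the lateral
## axis. Returns the 3x3 basis [lateral, hand axis, palm normal].
hand_basis <- function(sk, pose) {
  u <- unitv(sk$WRIST_R - sk$ELBOW_R, "forearm")
  up <- sk$SHOULDER_R - sk$ELBOW_R
  zf <- cross3(u, up)
  if (vnorm(zf) < 1e-9) zf <- cross3(u, c(1, 0, 0))
  zf <- unitv(zf, "flexion plane")
  n1 <- as.numeric(rot_axis(u, rad(pose$p)) %*% zf)
  ex1 <- cross3(u, n1)
  Rw <- rot_axis(ex1, -rad(pose$w))
  dh <- as.numeric(Rw %*% u)
  n2 <- as.numeric(Rw %*% n1)
  cbind(cross3(dh, n2), dh, n2)
}

## 21-point hand template (metres, wrist at origin, hand axis +y, palm
## normal +z). Finger curl is applied so that the measured bend angle of
## every finger equals `bend` exactly: the distal segment is the proximal
## chord rotated by `bend` towards the palm.
hand_template <- function(bend_deg) {
  phi <- rad(bend_deg)
  pts <- matrix(0, 21, 3)
  curl <- function(v) v * cos(phi) + c(0, 0, sin(phi)) * vnorm(v) / vnorm(v)
  rot_chord <- function(chord) chord * cos(phi) + c(0, 0, 1) * sin(phi)
  # thumb: landmarks 1-4 (rows 2-5); phalanx lengths are anatomical (~3 cm)
  # so that landmark jitter does not dominate the bend-angle derivative
  pts[2, ] <- c(0.022, 0.025, 0)
  pts[3, ] <- c(0.048, 0.058, 0)
  d02 <- pts[3, ] / vnorm(pts[3, ])
  pts[4, ] <- pts[3, ] + 0.030 * d02
  pts[5, ] <- pts[4, ] + 0.030 * rot_chord(d02)
  finger <- function(base, l1, l2, l3) {
    mcp <- base
    chord <- base / vnorm(base)
    pip <- mcp + l1 * chord
    dd <- rot_chord(chord)
    dip <- pip + l2 * dd
    tip <- dip + l3 * dd
    rbind(mcp, pip, dip, tip)
  }
  pts[6:9, ]   <- finger(c(0.025, 0.085, 0), 0.032, 0.022, 0.020)  # index
  pts[10:13, ] <- finger(c(0.000, 0.095, 0), 0.035, 0.024, 0.021)  # middle
  pts[14:17, ] <- finger(c(-0.022, 0.088, 0), 0.032, 0.022, 0.020) # ring
  pts[18:21, ] <- finger(c(-0.045, 0.075, 0), 0.026, 0.018, 0.017) # little
  pts
}

hand_world <- function(sk, pose) {
  B <- hand_basis(sk, pose)
  tpl <- hand_template(pose$bend)
  sweep(tpl %*% t(B), 2, sk$WRIST_R, `+`)
}

## ---- motion programs ------------------------------------------------------

min_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

BASE_POSE <- list(a = 10, b = 12, c = 0, e = 15, p = 0, w = 0, bend = 5,
                  sh_elev = 0, sh_ret = 0)

## Each motion program lists its baseline overrides, the animated parameter
## deltas, whether it is cyclic (sinusoidal, `cycles` over the clip), and
## whether a hand track is emitted.
MOTION_PROGRAMS <- list(
  M1 = list(base = list(), deltas = list(b = 55, c = 35, e = 80, p = -55,
                                         sh_elev = 14, sh_ret = 12),
            hand = TRUE),
  M2 = list(base = list(a = 25, b = 25, e = 95),
            deltas = list(c = -35, e = -80, p = 45, b = 10),
            hand = TRUE),
  M4 = list(base = list(a = 88), deltas = list(b = 84), hand = FALSE),
  M5 = list(base = list(b = 15, e = 35), deltas = list(e = -33), hand = FALSE),
  M6 = list(base = list(b = 10, e = 90), deltas = list(p = 45), cyclic = TRUE,
            cycles = 2, hand = TRUE),
  M7 = list(base = list(b = 10), deltas = list(e = 75), hand = FALSE),
  M8 = list(base = list(), deltas = list(b = 20), hand = FALSE),
  M9 = list(base = list(a = 8), deltas = list(b = 84), hand = FALSE),
  M10 = list(base = list(a = 88), deltas = list(b = 154), hand = FALSE),
  M11 = list(base = list(a = 60), deltas = list(b = 39), hand = FALSE),
  M12 = list(base = list(b = 12, e = 40), deltas = list(w = 30), hand = TRUE),
  M13 = list(base = list(b = 12, e = 90), deltas = list(w = 28), cyclic = TRUE,
             cycles = 2, hand = TRUE),
  M14 = list(base = list(b = 12, e = 60), deltas = list(bend = 80), hand = TRUE),
  M15 = list(base = list(b = 12, e = 60, bend = 85), deltas = list(bend = -77),
             hand = TRUE)
)

## Movement phase of the affected/healthy side: non-cyclic motions are
## minimum-jerk over `move_s / velocity_scale` seconds then hold; cyclic
## motions oscillate at `cycles / clip_s * velocity_scale` Hz.
phase_fun <- function(t, prog, prof, impaired) {
  v <- if (impaired) max(prof$velocity_scale, 1e-6) else 1
  if (isTRUE(prog$cyclic)) {
    f <- prog$cycles / prof$clip_s * v
    sin(2 * pi * f * t)
  } else {
    min_jerk(t * v / prof$move_s)
  }
}

tremor_wave <- function(t, amplitude) amplitude * sin(2 * pi * 6 * t)

build_arm_clip <- function(motion, prof, impaired) {
  prog <- MOTION_PROGRAMS[[motion]]
  n <- round(prof$clip_s * prof$fs)
  t <- (seq_len(n) - 1) / prof$fs
  s <- phase_fun(t, prog, prof, impaired)
  rs <- if (impaired) prof$rom_scale else 1
  trem <- if (impaired) tremor_wave(t, prof$tremor_amplitude) else 0 * t
  base <- utils::modifyList(BASE_POSE, prog$base)
  njoints <- c(names(static_skeleton()), "ELBOW_R", "WRIST_R", "HANDTIP_R")
  njoints <- setdiff(unique(njoints), "arm_R")
  joints <- lapply(njoints, function(j) matrix(NA_real_, n, 3))
  names(joints) <- njoints
  lm <- if (isTRUE(prog$hand)) array(NA_real_, c(n, 21, 3)) else NULL
  for (i in seq_len(n)) {
    pose <- base
    for (par in names(prog$deltas)) {
      delta <- prog$deltas[[par]] * rs * s[i]
      if (par %in% c("sh_elev", "sh_ret")) {     # no scapular tremor modelled
        pose[[par]] <- base[[par]] + delta
      } else {
        pose[[par]] <- base[[par]] + delta + trem[i]
      }
    }
    sk <- arm_joints(pose)
    if (isTRUE(prog$hand)) {
      hw <- hand_world(sk, pose)
      lm[i, , ] <- hw
      sk$HANDTIP_R <- hw[13, ]                  # middle fingertip
    } else {
      sk$HANDTIP_R <- sk$WRIST_R +
        0.10 * as.numeric(sk$arm_R %*% c(sin(rad(pose$e)), -cos(rad(pose$e)), 0))
    }
    sk$arm_R <- NULL
    for (j in names(sk)) joints[[j]][i, ] <- sk[[j]]
  }
  list(t = t, joints = joints, landmarks = lm)
}

## M3 (hand to lumbar spine) and M21 (finger-nose) animate trajectories
## directly: straight-line minimum-jerk reaches with stated completion.
build_reach_clip <- function(motion, prof, impaired) {
  n <- round(prof$clip_s * prof$fs)
  t <- (seq_len(n) - 1) / prof$fs
  s <- phase_fun(t, list(cyclic = FALSE), prof, impaired)
  rs <- if (impaired) prof$rom_scale else 1
  sk0 <- static_skeleton()
  joints_static <- sk0[setdiff(names(sk0), c("ELBOW_R", "WRIST_R", "HANDTIP_R"))]
  joints <- lapply(joints_static, function(p) matrix(p, n, 3, byrow = TRUE))
  if (motion == "M3") {
    hipc <- (sk0$HIP_L + sk0$HIP_R) / 2
    start <- c(0.32, 0.15, 0.20)
    target <- hipc + 0.04 * unitv(start - hipc)     # collinear approach
    frac <- 0.9 * rs                                # healthy closes 90%
    pos <- sapply(1:3, function(d) start[d] + frac * s * (target[d] - start[d]))
    joints$WRIST_R <- pos
    joints$HANDTIP_R <- sweep(pos, 2, c(0, -0.04, 0), `+`)
    joints$ELBOW_R <- sweep((pos + matrix(sk0$SHOULDER_R, n, 3, byrow = TRUE)) / 2,
                            2, c(0.03, 0, 0), `+`)
  } else {                                          # M21 finger-nose
    nose <- sk0$NOSE
    start <- nose + c(0.15, -0.35, 0.012)
    frac <- 0.9 * rs
    pos <- sapply(1:3, function(d) start[d] + frac * s * (nose[d] - start[d]))
    if (impaired && prof$tremor_amplitude > 0) {
      pos[, 2] <- pos[, 2] + 0.003 * tremor_wave(t, prof$tremor_amplitude)
    }
    joints$HANDTIP_R <- pos
    joints$WRIST_R <- sweep(pos, 2, c(-0.02, -0.09, 0), `+`)
    joints$ELBOW_R <- sweep((pos + matrix(sk0$SHOULDER_R, n, 3, byrow = TRUE)) / 2,
                            2, c(0.05, -0.05, 0), `+`)
  }
  list(t = t, joints = joints, landmarks = NULL)
}

## Tracker jitter is band-limited, not white: model-based markerless
## trackers (skeleton solvers, hand-landmark regressors with temporal
## filtering) produce slowly wandering position errors rather than
## per-frame-independent noise. Jitter is therefore drawn as Gaussian noise
## low-passed at 1 Hz and rescaled to the requested amplitude.
band_noise <- function(n, fs, sd0) {
  w <- stats::rnorm(n)
  f <- lowpass(w, filter_spec(order = 2, cutoff_hz = 1, fs = fs))
  s <- stats::sd(f)
  if (s < 1e-12) return(rep(0, n))
  f * sd0 / s
}

add_noise <- function(clipdata, sd, fs) {
  if (sd > 0) {
    n <- length(clipdata$t)
    for (j in names(clipdata$joints)) {
      for (d in 1:3) {
        clipdata$joints[[j]][, d] <- clipdata$joints[[j]][, d] +
          band_noise(n, fs, sd)
      }
    }
    if (!is.null(clipdata$landmarks)) {
      for (k in 1:21) for (d in 1:3) {
        clipdata$landmarks[, k, d] <- clipdata$landmarks[, k, d] +
          band_noise(n, fs, sd)
      }
    }
  }
  clipdata
}

make_clip <- function(motion, side, prof) {
  impaired <- side == "affected"
  cd <- if (motion %in% c("M3", "M21")) {
    build_reach_clip(motion, prof, impaired)
  } else {
    build_arm_clip(motion, prof, impaired)
  }
  cd <- add_noise(cd, prof$noise_sd, prof$fs)
  hand <- if (!is.null(cd$landmarks)) hand_track(cd$t, cd$landmarks) else NULL
  motion_clip(motion, side, prof$fs, body_track(cd$t, cd$joints), hand)
}

## ---- force-grid generator -------------------------------------------------

FINGER_BLOBS <- data.frame(
  finger = c("thumb", "index", "middle", "ring", "little"),
  row = c(12, 5, 4, 5, 6),
  col = c(4, 6, 8, 10, 12),
  peak = c(12.2, 7.6, 6.3, 4.1, 3.6),   # newtons, healthy-hand fingertips
  sigma = c(0.5, 0.45, 0.45, 0.45, 0.45)
)
PALM_BLOB <- list(row = 10, col = 8, peak = 1.6, sigma = 1.5)

gauss_blob <- function(row, col, peak, sigma) {
  r <- matrix(1:16, 16, 16)
  cc <- matrix(1:16, 16, 16, byrow = TRUE)
  peak * exp(-((r - row)^2 + (cc - col)^2) / (2 * sigma^2))
}

healthy_grip_grid <- function() {
  g <- matrix(0, 16, 16)
  for (i in seq_len(nrow(FINGER_BLOBS))) {
    b <- FINGER_BLOBS[i, ]
    g <- g + gauss_blob(b$row, b$col, b$peak, b$sigma)
  }
  g + gauss_blob(PALM_BLOB$row, PALM_BLOB$col, PALM_BLOB$peak, PALM_BLOB$sigma)
}

affected_grip_grid <- function(prof) {
  g <- matrix(0, 16, 16)
  for (i in seq_len(nrow(FINGER_BLOBS))) {
    b <- FINGER_BLOBS[i, ]
    if (b$finger %in% prof$disabled_fingers) next
    g <- g + gauss_blob(b$row, b$col, b$peak, b$sigma)
  }
  g <- g + gauss_blob(PALM_BLOB$row, PALM_BLOB$col, PALM_BLOB$peak, PALM_BLOB$sigma)
  g * prof$force_scale
}

#' Generate synthetic pressure-grid frames for one grasp motion
#'
#' The healthy grid carries five fingertip contact blobs (thumb strongest,
#' around 12 N) plus a broad low palm-contact area; the affected grid is
#' the same layout scaled by `force_scale` with disabled fingers' blobs
#' removed. Frames ramp up over time so the per-cell maximum recovers the
#' full grid. The healthy hand is the contralateral (left) hand, so its
#' print is column-mirrored.
#'
#' @param profile an [impairment_profile()].
#' @param motion one of `FORCE_MOTIONS` (M16-M20).
#' @param n_frames frames per sequence.
#' @return List of [force_frame()] objects (both sides).
#' @export
gen_force_frames <- function(profile, motion, n_frames = 8) {
  if (!motion %in% FORCE_MOTIONS) {
    stop_autofma("motion must be one of %s", paste(FORCE_MOTIONS, collapse = ", "),
                 class = "autofma_parameter_error")
  }
  tt <- seq(0.1, by = 0.1, length.out = n_frames)
  ramp <- min_jerk(seq(0, 1, length.out = n_frames))
  gh <- healthy_grip_grid()[, 16:1]               # left hand: mirrored print
  ga <- affected_grip_grid(profile)
  frames <- list()
  for (i in seq_len(n_frames)) {
    # matrix first: pmax copies dim attributes from its first argument
    na_ <- pmax(ga * ramp[i] +
                  matrix(stats::rnorm(256, 0, profile$noise_sd), 16, 16), 0)
    nh_ <- pmax(gh * ramp[i] +
                  matrix(stats::rnorm(256, 0, profile$noise_sd), 16, 16), 0)
    frames[[2 * i - 1]] <- force_frame(tt[i], na_, motion, "affected")
    frames[[2 * i]] <- force_frame(tt[i], nh_, motion, "healthy")
  }
  frames
}

#' Generate a complete synthetic recording
#'
#' Builds paired affected/healthy clips for all body motions (M1-M15, M21)
#' and force-frame sequences for the five grasp motions (M16-M20). The
#' affected side is the right limb; healthy clips are stored as the
#' (mirrored) left limb, exercising the load-time canonicalisation path.
#'
#' @param profile an [impairment_profile()].
#' @param subject_id subject identifier stored in the recording.
#' @return A [fma_recording()].
#' @export
gen_recording <- function(profile = impairment_profile(), subject_id = "synthetic") {
  stopifnot(inherits(profile, "impairment_profile"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(profile$seed)
  body_motions <- c(paste0("M", 1:15), "M21")
  body_motions <- setdiff(body_motions, FORCE_MOTIONS)
  clips <- list()
  for (m in body_motions) {
    clips[[length(clips) + 1]] <- make_clip(m, "affected", profile)
    healthy <- make_clip(m, "healthy", profile)
    clips[[length(clips) + 1]] <- mirror_clip(healthy)  # stored as left limb
  }
  frames <- list()
  for (m in FORCE_MOTIONS) {
    frames <- c(frames, gen_force_frames(profile, m))
  }
  fma_recording(subject_id, "right", clips, frames)
}
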