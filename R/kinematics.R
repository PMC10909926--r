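## Joint coordinate systems and joint-angle traces.
##
## Thorax and shoulder triads follow ISB conventions adapted to the
## Kinect-style joint set; shoulder angles come from a Y-X-Y (plane of
## elevation / elevation / axial rotation) Euler decomposition of the
## thorax-to-humerus rotation, mapped to clinical flexion/abduction/rotation.
## All angles are reported in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    stop_autofma("degenerate geometry: zero-length %s", what,
                 class = "autofma_geometry_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Construct an orthonormal right-handed frame triad
#'
#' @param origin 3-D origin in metres.
#' @param X,Y,Z unit axis vectors; must be orthonormal with `det = +1`
#'   within 1e-9.
#' @return A `frame_triad` object.
#' @export
frame_triad <- function(origin, X, Y, Z) {
  M <- cbind(X, Y, Z)
  if (max(abs(crossprod(M) - diag(3))) > 1e-9 || abs(det(M) - 1) > 1e-9) {
    stop_autofma("frame axes are not right-handed orthonormal",
                 class = "autofma_geometry_error")
  }
  structure(list(origin = origin, X = X, Y = Y, Z = Z), class = "frame_triad")
}

triad_matrix <- function(f) cbind(f$X, f$Y, f$Z)

joint_at <- function(clip, name, i) {
  m <- clip$body$joints[[name]]
  if (is.null(m)) {
    stop_autofma("required joint %s missing from clip %s/%s",
                 name, clip$motion_id, clip$side,
                 class = "autofma_missing_joint_error")
  }
  m[i, ]
}

#' Thorax coordinate system from one body sample
#'
#' `Y_T` is the unit vector from the spine-chest joint to the neck; the
#' anterior axis `X_T` is the normal of the plane spanned by `Y_T` and a
#' trunk-fixed lateral line, oriented ventrally; `Z_T = X_T x Y_T` points
#' to the subject's right. The lateral line is the inter-hip line when both
#' hips are present, otherwise the inter-shoulder line: the pelvis is rigid
#' with the trunk, whereas scapular elevation/retraction moves the
#' shoulders and would rotate the reference frame the scapular items are
#' measured against.
#'
#' @param joints named list of 3-D positions containing `SPINE_CHEST` and
#'   `NECK`, plus `HIP_L`/`HIP_R` (preferred) or `SHOULDER_L`/`SHOULDER_R`.
#' @return A [frame_triad()] at the spine-chest origin.
#' @export
thorax_frame <- function(joints) {
  Y <- unitv(joints$NECK - joints$SPINE_CHEST, "spine-chest to neck axis")
  s <- if (!is.null(joints$HIP_L) && !is.null(joints$HIP_R)) {
    joints$HIP_R - joints$HIP_L
  } else {
    joints$SHOULDER_R - joints$SHOULDER_L
  }
  X <- unitv(cross3(Y, s), "thorax anterior axis")
  Z <- cross3(X, Y)
  frame_triad(joints$SPINE_CHEST, X, Y, Z)
}

#' Shoulder (humerus) coordinate system from one body sample
#'
#' `Y_S` runs from the elbow to the shoulder. The floating anterior axis
#' `X_S` is the forearm direction projected perpendicular to `Y_S` (the
#' elbow flexion plane defines the humeral axial reference); with a
#' straight arm this projection degenerates and the thorax anterior axis
#' is projected instead. `Z_S = X_S x Y_S` completes a right-handed triad.
#'
#' @param joints named list with `SHOULDER_R`, `ELBOW_R`, `WRIST_R` (right
#'   limb after canonicalisation).
#' @param thorax the thorax [frame_triad()] of the same sample (fallback
#'   reference for the degenerate straight-arm case).
#' @return A [frame_triad()] at the shoulder origin.
#' @export
shoulder_frame <- function(joints, thorax) {
  Y <- unitv(joints$SHOULDER_R - joints$ELBOW_R, "humerus axis")
  f <- joints$WRIST_R - joints$ELBOW_R
  fp <- f - sum(f * Y) * Y
  if (vnorm(fp) < 1e-6) {           # straight arm: fall back to thorax anterior
    fp <- thorax$X - sum(thorax$X * Y) * Y
  }
  X <- unitv(fp, "shoulder anterior axis")
  Z <- cross3(X, Y)
  frame_triad(joints$SHOULDER_R, X, Y, Z)
}

#' Shoulder angles from thorax and shoulder triads
#'
#' Decomposes the relative rotation `R = t(T) %*% S` with the ISB Y-X-Y
#' sequence (plane of elevation, elevation, axial rotation) and maps the
#' result onto clinical labels: `flexion = elevation * sin(plane)`,
#' `abduction = elevation * cos(plane)`, `rotation` = axial rotation
#' (internal positive). Near the `elevation = 0` singularity the full
#' rotation is assigned deterministically to the plane-of-elevation angle.
#'
#' @param thorax,shoulder [frame_triad()] objects.
#' @return Named numeric vector `c(flexion, abduction, rotation)` in degrees.
#' @export
shoulder_angles <- function(thorax, shoulder) {
  R <- t(triad_matrix(thorax)) %*% triad_matrix(shoulder)
  ys <- R[, 2]                               # humerus axis in thorax coords
  b <- acos(clamp1(ys[2]))                   # elevation from vertical
  sb <- sqrt(max(0, 1 - ys[2]^2))
  if (sb < 1e-8) {                           # gimbal: arm along thorax Y
    a <- atan2(R[1, 3], R[1, 1])
    cc <- 0
  } else {
    # plane of elevation measured from the shoulder-to-elbow direction
    # (-Y_S), so lateral elevation of the right arm is abduction-positive
    # and anterior elevation is flexion-positive
    a <- atan2(-ys[1], -ys[3])
    Rc <- rot_x(b) %*% rot_y(-a) %*% R       # what remains is Ry(c)
    cc <- atan2(Rc[1, 3], Rc[1, 1])
  }
  c(flexion = deg(b) * sin(a),
    abduction = deg(b) * cos(a),
    rotation = deg(cc))
}

rot_x <- function(th) {
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(th) {
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' Elbow flexion angle
#'
#' Angle between the upper arm and the forearm, reported as
#' `180 - interior angle`, so a fully extended arm reads 0 degrees.
#'
#' @param joints named list with `SHOULDER_R`, `ELBOW_R`, `WRIST_R`.
#' @return Flexion angle in degrees, in `[0, 180]`.
#' @export
elbow_flexion <- function(joints) {
  u <- unitv(joints$SHOULDER_R - joints$ELBOW_R, "upper arm")
  f <- unitv(joints$WRIST_R - joints$ELBOW_R, "forearm")
  180 - deg(acos(clamp1(sum(u * f))))
}

#' Shoulder elevation and retraction angles
#'
#' Both come from the shoulder-to-neck vector expressed in the thorax
#' frame: elevation is its (signed) angle above the horizontal plane,
#' retraction its signed angle behind the frontal plane.
#'
#' @param joints named list with `NECK`, `SHOULDER_R` plus the thorax joints.
#' @return Named vector `c(elevation, retraction)` in degrees.
#' @export
shoulder_elevation_retraction <- function(joints) {
  thx <- thorax_frame(joints)
  v <- unitv(joints$SHOULDER_R - joints$NECK, "shoulder-neck vector")
  c(elevation = deg(asin(clamp1(sum(v * thx$Y)))),
    retraction = deg(asin(clamp1(-sum(v * thx$X)))))
}

palm_normal <- function(hand_lm) {
  unitv(cross3(hand_lm[6, ] - hand_lm[1, ], hand_lm[18, ] - hand_lm[1, ]),
        "palm plane")
}

#' Wrist flexion/extension angle from body and hand
#'
#' Signed angle between the forearm axis (elbow to wrist) and the hand axis
#' (landmark 0 to landmark 9), dorsiflexion positive; the sign is resolved
#' against the palm normal built from landmarks 0, 5 and 17.
#'
#' @param joints named list with `ELBOW_R`, `WRIST_R`.
#' @param hand_lm `21 x 3` aligned hand-landmark matrix.
#' @return Wrist angle in degrees (dorsiflexion positive).
#' @export
wrist_flexion_angle <- function(joints, hand_lm) {
  u <- unitv(joints$WRIST_R - joints$ELBOW_R, "forearm axis")
  h <- unitv(hand_lm[10, ] - hand_lm[1, ], "hand axis")
  ang <- deg(acos(clamp1(sum(u * h))))
  n <- palm_normal(hand_lm)
  perp <- h - sum(h * u) * u
  if (vnorm(perp) < 1e-9) return(0)
  sgn <- if (sum(perp * (-n)) >= 0) 1 else -1
  sgn * ang
}

#' Forearm pronation/supination angle (relative to clip start)
#'
#' The palm normal is compared, about the forearm axis, with the elbow
#' flexion-plane normal (forearm x upper arm). The angle is reported
#' relative to the first sample of the clip, since the protocol tracks
#' rotation during a motion rather than an absolute anatomical zero.
#' This function returns the absolute angle for one sample; the trace
#' builder subtracts the starting value and unwraps.
#'
#' @inheritParams wrist_flexion_angle
#' @param thorax thorax [frame_triad()] (fallback reference when the elbow
#'   is straight).
#' @return Rotation angle about the forearm axis, degrees in `(-180, 180]`.
#' @export
forearm_rotation_angle <- function(joints, hand_lm, thorax) {
  u <- unitv(joints$WRIST_R - joints$ELBOW_R, "forearm axis")
  up <- joints$SHOULDER_R - joints$ELBOW_R
  zf <- cross3(u, up)
  if (vnorm(zf) < 1e-6) zf <- cross3(u, thorax$X)
  zf <- unitv(zf, "flexion-plane normal")
  n <- palm_normal(hand_lm)
  p1 <- zf - sum(zf * u) * u
  p2 <- n - sum(n * u) * u
  if (vnorm(p1) < 1e-9 || vnorm(p2) < 1e-9) return(0)
  deg(atan2(sum(cross3(p1, p2) * u), sum(p1 * p2)))
}

#' Finger bend angle from hand landmarks
#'
#' The bend of each finger is the 3-D angle between a proximal chord and
#' the distal segment of that finger (thumb: vectors 3-4 vs 0-2; index:
#' 0-6 vs 7-8; middle: 0-9 vs 10-12; ring: 0-13 vs 14-16; little:
#' 0-17 vs 18-20, in the 21-point hand numbering).
#'
#' @param hand_lm `21 x 3` hand-landmark matrix.
#' @param finger one of `"thumb"`, `"index"`, `"middle"`, `"ring"`, `"little"`.
#' @return Bend angle in degrees, in `[0, 180]`.
#' @export
finger_bend_angle <- function(hand_lm,
                              finger = c("thumb", "index", "middle", "ring", "little")) {
  finger <- match.arg(finger)
  idx <- switch(finger,                       # 1-based landmark indices
    thumb  = list(v1 = c(4, 5),  v2 = c(1, 3)),
    index  = list(v1 = c(1, 7),  v2 = c(8, 9)),
    middle = list(v1 = c(1, 10), v2 = c(11, 13)),
    ring   = list(v1 = c(1, 14), v2 = c(15, 17)),
    little = list(v1 = c(1, 18), v2 = c(19, 21))
  )
  v1 <- unitv(hand_lm[idx$v1[2], ] - hand_lm[idx$v1[1], ], "finger chord")
  v2 <- unitv(hand_lm[idx$v2[2], ] - hand_lm[idx$v2[1], ], "finger segment")
  deg(acos(clamp1(sum(v1 * v2))))
}

unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  cumsum(c(x[1], d))
}

ANGLE_LABELS <- c("shoulder_elevation", "shoulder_retraction", "shoulder_flexion",
                  "shoulder_abduction", "shoulder_rotation", "elbow_flexion",
                  "forearm_pronation", "wrist_flexion",
                  "finger_bend_thumb", "finger_bend_four_mean")

#' Compute joint-angle traces for a clip
#'
#' The clip must be canonicalised to the right limb; position channels are
#' expected to be filtered (see [filter_clip()]) and the hand track, when
#' needed, aligned (see [align_clip_hand()]). Signed traces
#' (`forearm_pronation`, `shoulder_rotation`, `wrist_flexion`) are
#' unwrapped; `forearm_pronation` is additionally referenced to the clip's
#' first sample.
#'
#' @param clip a prepared [motion_clip()].
#' @param labels character vector of angle labels (subset of the published
#'   vocabulary, see [angle_label_registry()]).
#' @return List with `t`, `fs` and `traces` (named list of numeric vectors,
#'   degrees).
#' @export
angle_traces <- function(clip, labels) {
  bad <- setdiff(labels, ANGLE_LABELS)
  if (length(bad)) {
    stop_autofma("unknown angle label(s): %s", paste(bad, collapse = ", "),
                 class = "autofma_parameter_error")
  }
  need_hand <- intersect(labels, c("forearm_pronation", "wrist_flexion",
                                   "finger_bend_thumb", "finger_bend_four_mean"))
  if (length(need_hand) && is.null(clip$hand)) {
    stop_autofma("clip %s/%s has no hand track; label(s) unavailable: %s",
                 clip$motion_id, clip$side, paste(need_hand, collapse = ", "),
                 class = "autofma_unavailable_feature_error")
  }
  n <- length(clip$body$t)
  out <- lapply(labels, function(l) numeric(n))
  names(out) <- labels
  need_euler <- any(labels %in% c("shoulder_flexion", "shoulder_abduction",
                                  "shoulder_rotation"))
  for (i in seq_len(n)) {
    joints <- lapply(clip$body$joints, function(m) m[i, ])
    thx <- thorax_frame(joints)
    if (need_euler) {
      ang <- shoulder_angles(thx, shoulder_frame(joints, thx))
    }
    if (any(labels %in% c("shoulder_elevation", "shoulder_retraction"))) {
      er <- shoulder_elevation_retraction(joints)
    }
    hl <- if (length(need_hand)) clip$hand$landmarks[i, , ] else NULL
    for (l in labels) {
      out[[l]][i] <- switch(l,
        shoulder_elevation = er[["elevation"]],
        shoulder_retraction = er[["retraction"]],
        shoulder_flexion = ang[["flexion"]],
        shoulder_abduction = ang[["abduction"]],
        shoulder_rotation = ang[["rotation"]],
        elbow_flexion = elbow_flexion(joints),
        forearm_pronation = forearm_rotation_angle(joints, hl, thx),
        wrist_flexion = wrist_flexion_angle(joints, hl),
        finger_bend_thumb = finger_bend_angle(hl, "thumb"),
        finger_bend_four_mean = mean(c(finger_bend_angle(hl, "index"),
                                       finger_bend_angle(hl, "middle"),
                                       finger_bend_angle(hl, "ring"),
                                       finger_bend_angle(hl, "little")))
      )
    }
  }
  for (l in intersect(labels, c("forearm_pronation", "shoulder_rotation",
                                "wrist_flexion"))) {
    out[[l]] <- unwrap_deg(out[[l]])
  }
  if ("forearm_pronation" %in% labels) {
    out$forearm_pronation <- out$forearm_pronation - out$forearm_pronation[1]
  }
  list(t = clip$body$t, fs = clip$fs, traces = out)
}

#' Angle-label registry
#'
#' Machine-readable table mapping each angle label to the inputs it needs;
#' consumed by the item registry.
#'
#' @return data.frame with columns `label`, `needs_hand`.
#' @export
angle_label_registry <- function() {
  data.frame(
    label = ANGLE_LABELS,
    needs_hand = ANGLE_LABELS %in% c("forearm_pronation", "wrist_flexion",
                                     "finger_bend_thumb", "finger_bend_four_mean"),
    stringsAsFactors = FALSE
  )
}
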