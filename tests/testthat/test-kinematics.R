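test_that("thorax frame axes follow the trunk", {
  j <- basic_joints()
  f <- thorax_frame(j)
  expect_equal(f$Y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(f$X, c(1, 0, 0), tolerance = 1e-12)   # anterior
  expect_equal(f$Z, c(0, 0, 1), tolerance = 1e-12)   # right-lateral
  # trunk leaned 30 degrees about the anterior axis
  R <- autofma:::rot_x(pi / 6)
  j2 <- lapply(j, function(p) as.numeric(R %*% p))
  f2 <- thorax_frame(j2)
  expect_equal(acos(sum(f2$Y * c(0, 1, 0))) * 180 / pi, 30, tolerance = 1e-8)
  # coincident landmarks are degenerate
  j3 <- j; j3$NECK <- j3$SPINE_CHEST
  expect_error(thorax_frame(j3), class = "autofma_geometry_error")
})

test_that("frames are rigid-rotation equivariant and right-handed", {
  set.seed(5)
  j <- basic_joints()
  for (rep in 1:5) {
    R <- random_rotation()
    v <- rnorm(3)
    j2 <- lapply(j, function(p) as.numeric(R %*% p) + v)
    f <- thorax_frame(j); f2 <- thorax_frame(j2)
    expect_equal(f2$X, as.numeric(R %*% f$X), tolerance = 1e-9)
    expect_equal(f2$Y, as.numeric(R %*% f$Y), tolerance = 1e-9)
    expect_equal(f2$Z, as.numeric(R %*% f$Z), tolerance = 1e-9)
    s <- shoulder_frame(j, f); s2 <- shoulder_frame(j2, f2)
    expect_equal(s2$Y, as.numeric(R %*% s$Y), tolerance = 1e-9)
    M <- autofma:::triad_matrix(s2)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
})

test_that("shoulder frame orientation in canonical poses", {
  j <- basic_joints()
  thx <- thorax_frame(j)
  # arm hanging straight down: humerus axis points up
  j$ELBOW_R <- j$SHOULDER_R + c(0, -0.28, 0)
  j$WRIST_R <- j$ELBOW_R + c(0.25, 0, 0)
  s <- shoulder_frame(j, thx)
  expect_equal(s$Y, c(0, 1, 0), tolerance = 1e-9)
  # arm abducted 90 degrees laterally: humerus axis horizontal
  j2 <- j
  j2$ELBOW_R <- j2$SHOULDER_R + c(0, 0, 0.28)
  j2$WRIST_R <- j2$ELBOW_R + c(0.25, 0, 0)
  s2 <- shoulder_frame(j2, thorax_frame(j2))
  expect_equal(s2$Y, c(0, 0, -1), tolerance = 1e-9)
  expect_equal(abs(sum(s2$Y * c(0, 1, 0))), 0, tolerance = 1e-9)
})

test_that("shoulder Euler angles: identity, pure abduction, reconstruction", {
  j <- basic_joints()
  thx <- thorax_frame(j)
  # identical triads -> all zero
  a0 <- shoulder_angles(thx, thx)
  expect_equal(unname(a0), c(0, 0, 0), tolerance = 1e-7)
  # constructed pure 90-degree abduction (elbow bent anteriorly)
  j2 <- j
  j2$ELBOW_R <- j2$SHOULDER_R + c(0, 0, 0.28)
  j2$WRIST_R <- j2$ELBOW_R + c(0.25, 0, 0)
  ang <- shoulder_angles(thx, shoulder_frame(j2, thx))
  expect_equal(ang[["abduction"]], 90, tolerance = 1e-6)
  expect_equal(ang[["flexion"]], 0, tolerance = 1e-6)
  expect_equal(ang[["rotation"]], 0, tolerance = 1e-6)
  # decomposition round-trip: rebuild R from (plane, elevation, axial)
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, -pi, pi); b <- runif(1, 0.05, pi - 0.05); cc <- runif(1, -pi, pi)
    R <- autofma:::rot_y(a) %*% autofma:::rot_x(-b) %*% autofma:::rot_y(cc)
    S <- frame_triad(c(0, 0, 0), R[, 1], R[, 2], R[, 3])
    Tt <- frame_triad(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    ang <- shoulder_angles(Tt, S)
    b_deg <- b * 180 / pi
    expect_equal(ang[["flexion"]], b_deg * sin(a), tolerance = 1e-6)
    expect_equal(ang[["abduction"]], b_deg * cos(a), tolerance = 1e-6)
    rot_wrapped <- ((ang[["rotation"]] - cc * 180 / pi + 180) %% 360) - 180
    expect_equal(rot_wrapped, 0, tolerance = 1e-6)
  }
})

test_that("elbow flexion matches the interior-angle oracle", {
  j <- basic_joints()
  # straight (collinear) arm -> 0
  j$ELBOW_R <- j$SHOULDER_R + c(0, -0.28, 0)
  j$WRIST_R <- j$ELBOW_R + c(0, -0.25, 0)
  expect_equal(elbow_flexion(j), 0, tolerance = 1e-7)
  # right-angle bend -> 90
  j$WRIST_R <- j$ELBOW_R + c(0.25, 0, 0)
  expect_equal(elbow_flexion(j), 90, tolerance = 1e-7)
  # random non-degenerate triples against the acos oracle
  set.seed(3)
  for (i in 1:20) {
    j$SHOULDER_R <- rnorm(3); j$ELBOW_R <- rnorm(3); j$WRIST_R <- rnorm(3)
    u <- j$SHOULDER_R - j$ELBOW_R; v <- j$WRIST_R - j$ELBOW_R
    oracle <- 180 - acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(elbow_flexion(j), oracle, tolerance = 1e-8)
  }
})

test_that("shoulder elevation/retraction from constructed poses", {
  j <- basic_joints()
  # shoulder level with the neck, purely lateral -> (0, 0)
  j$SHOULDER_R <- j$NECK + c(0, 0, 0.18)
  er <- shoulder_elevation_retraction(j)
  expect_equal(unname(er), c(0, 0), tolerance = 1e-8)
  # raised so the shoulder-neck vector makes 20 degrees with horizontal
  j$SHOULDER_R <- j$NECK + 0.18 * c(0, sin(20 * pi / 180), cos(20 * pi / 180))
  expect_equal(shoulder_elevation_retraction(j)[["elevation"]], 20,
               tolerance = 1e-6)
  # pulled back 15 degrees behind the frontal plane
  j$SHOULDER_R <- j$NECK + 0.18 * c(-sin(15 * pi / 180), 0, cos(15 * pi / 180))
  expect_equal(shoulder_elevation_retraction(j)[["retraction"]], 15,
               tolerance = 1e-6)
})

test_that("finger bend angles: straight, perpendicular, planar formula", {
  lm0 <- hand_template_like(0)
  for (f in c("thumb", "index", "middle", "ring", "little")) {
    expect_lt(finger_bend_angle(lm0, f), 1e-4)   # acos accuracy near 1
  }
  lm90 <- hand_template_like(90)
  expect_equal(finger_bend_angle(lm90, "index"), 90, tolerance = 1e-7)
  # planar landmarks (z = 0): the 3-D arccos implementation reproduces the
  # printed 2-D arccos expression exactly
  set.seed(21)
  for (i in 1:10) {
    lm <- cbind(matrix(rnorm(42, sd = 0.05), 21, 2), 0)
    lm[1, ] <- 0
    x <- lm[, 1]; y <- lm[, 2]
    num <- (x[5] - x[4]) * (x[3] - x[1]) + (y[5] - y[4]) * (y[3] - y[1])
    den <- sqrt((x[5] - x[4])^2 + (y[5] - y[4])^2) *
      sqrt((x[3] - x[1])^2 + (y[3] - y[1])^2)
    theta2d <- acos(pmin(1, pmax(-1, num / den))) * 180 / pi
    expect_equal(finger_bend_angle(lm, "thumb"), theta2d, tolerance = 1e-8)
  }
})

test_that("angle traces are invariant under rigid motion of all joints", {
  prof <- impairment_profile(noise_sd = 0, seed = 1)
  clip <- autofma:::make_clip("M1", "affected", prof)
  clip <- filter_clip(clip)
  clip <- align_clip_hand(clip)
  labels <- c("shoulder_elevation", "shoulder_retraction", "shoulder_abduction",
              "shoulder_rotation", "elbow_flexion", "forearm_pronation")
  tr <- angle_traces(clip, labels)
  set.seed(9)
  R <- random_rotation(); v <- rnorm(3)
  tr2 <- angle_traces(transform_clip(clip, R, v), labels)
  for (l in labels) {
    expect_lt(max(abs(tr2$traces[[l]] - tr$traces[[l]])), 1e-6)
  }
})

test_that("static pose gives constant traces; missing hand is reported", {
  clip <- static_clip(n = 30)
  tr <- angle_traces(clip, c("elbow_flexion", "shoulder_abduction"))
  for (l in names(tr$traces)) {
    expect_lt(diff(range(tr$traces[[l]])), 1e-9)
  }
  expect_error(angle_traces(clip, "wrist_flexion"),
               class = "autofma_unavailable_feature_error")
})
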