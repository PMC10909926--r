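test_that("ROM, mean velocity and excursion basics", {
  expect_equal(rom(rep(4.2, 50)), 0)
  expect_equal(rom(c(1, 7, 19, 3)), 18)        # trace spanning 1-19 degrees
  t <- seq(0, 2, by = 0.01)
  expect_equal(rom(3.5 * sin(2 * pi * t)), 7, tolerance = 1e-3)
  expect_equal(mean_velocity(rep(1, 10), 30), 0)
  # linear ramp at r deg/s
  fs <- 30; r <- 12
  ramp <- r * (0:59) / fs
  expect_equal(mean_velocity(ramp, fs), r, tolerance = 1e-9)
  # triangle wave of slope +/- s
  tri <- c(seq(0, 10, length.out = 31), seq(10, 0, length.out = 31)[-1])
  s <- 10 / 30 * fs
  expect_equal(mean_velocity(tri, fs), s, tolerance = 1e-9)
  expect_equal(max_excursion(c(5, 3, 9, 5)), 4)
  expect_error(mean_velocity(1, 30), class = "autofma_length_error")
})

test_that("side-to-side deviation matches hand evaluation and RMS properties", {
  expect_equal(deviation_sd(1:50, 1:50), 0)
  expect_equal(deviation_sd(c(3, 4), c(0, 0), n = 2), sqrt((9 + 16) / 2))
  expect_equal(deviation_sd(c(3, 4), c(0, 0), n = 2), 3.5355, tolerance = 1e-4)
  # constant offset c -> |c|
  x <- sin(seq(0, 3, length.out = 40))
  expect_equal(deviation_sd(x + 2.5, x), 2.5, tolerance = 1e-9)
  # triangle-like bound through any middle trace
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(30); h <- rnorm(30); m <- rnorm(30)
    expect_lte(deviation_sd(a, h),
               deviation_sd(a, m) + deviation_sd(m, h) + 1e-12)
  }
})

test_that("hand-to-hip ratio arithmetic", {
  hipc <- c(0, -0.05, 0)
  mk <- function(dists) {
    # wrist moving along +x from the hip centre at controlled distances
    frames <- lapply(dists, function(d) {
      j <- basic_joints()
      j$WRIST_R <- hipc + c(d, 0, 0)
      j
    })
    clip_from_frames(frames, motion_id = "M3")
  }
  r <- hand_hip_ratio(mk(c(0.5, 0.3, 0.1, 0.2)))
  expect_equal(r$alpha, 0.2)                    # 0.1 / 0.5
  expect_equal(r$completion, 0.8)
  expect_equal(hand_hip_ratio(mk(rep(0.4, 5)))$alpha, 1)   # hand never moves
  expect_error(hand_hip_ratio(mk(c(1e-9, 0.1))),
               class = "autofma_degenerate_start_error")
})

test_that("finger-nose reach features on a constructed constant-speed reach", {
  fs <- 30
  n <- 60
  j0 <- basic_joints()
  v <- 0.35                                     # m/s straight-line speed
  frames <- lapply(seq_len(n), function(i) {
    j <- j0
    dy <- min((i - 1) / fs * v, 0.35)           # rises 0.35 m then holds
    j$HANDTIP_R <- c(0.10, 0.35 + dy, 0)        # straight below the nose
    j$WRIST_R <- j$HANDTIP_R - c(0, 0.09, 0)
    j
  })
  clip <- clip_from_frames(frames, motion_id = "M21")
  f <- finger_nose_features(clip)
  expect_equal(f$vmax, v, tolerance = 1e-6)
  expect_equal(f$gamma_min, 0, tolerance = 1e-9)  # reaches nose height
  expect_equal(f$completion, 1, tolerance = 1e-9)
  expect_equal(f$beta, 1, tolerance = 1e-6)       # midline -> symmetric
  # no movement: gamma stays 1, features floored to zero
  still <- clip_from_frames(rep(list(frames[[1]]), 30), motion_id = "M21")
  f0 <- finger_nose_features(still)
  expect_equal(f0$gamma_min, 1)
  expect_equal(f0$vmax, 0)
  expect_equal(f0$ma, 0)
})

test_that("grip force total: threshold, arithmetic, monotonicity", {
  z <- list(force_frame(0, matrix(0, 16, 16), "M19", "affected"))
  expect_equal(grip_force_total(z)$total_force, 0)
  g <- matrix(0, 16, 16); g[4, 7] <- 5
  expect_equal(grip_force_total(list(force_frame(0, g, "M19", "affected")),
                                0.1)$total_force, 5)
  # three cells above threshold, others below -> 13.0 N
  g2 <- matrix(0.05, 16, 16)
  g2[3, 3] <- 5.1; g2[3, 8] <- 4.5; g2[4, 10] <- 3.4
  expect_equal(grip_force_total(list(force_frame(0, g2, "M19", "affected")),
                                0.1)$total_force, 13.0)
  # per-cell maximum over frames
  f1 <- force_frame(0, g, "M19", "affected")
  g3 <- matrix(0, 16, 16); g3[4, 7] <- 2; g3[9, 9] <- 1
  f2 <- force_frame(1, g3, "M19", "affected")
  expect_equal(grip_force_total(list(f1, f2), 0.1)$total_force, 6)
  # monotone: raising a cell never lowers the total; raising the threshold
  # never raises it
  set.seed(8)
  gr <- matrix(runif(256, 0, 2), 16, 16)
  base <- grip_force_total(list(force_frame(0, gr, "M19", "affected")), 0.3)
  gr2 <- gr; gr2[5, 5] <- gr2[5, 5] + 1
  up <- grip_force_total(list(force_frame(0, gr2, "M19", "affected")), 0.3)
  expect_gte(up$total_force, base$total_force)
  hi <- grip_force_total(list(force_frame(0, gr, "M19", "affected")), 0.6)
  expect_lte(hi$total_force, base$total_force)
  expect_error(grip_force_total(list()), class = "autofma_length_error")
})

test_that("force-frame mirroring is a column flip and an involution", {
  g <- matrix(0, 16, 16); g[7, 1] <- 3
  fr <- force_frame(0, g, "M19", "healthy")
  m <- mirror_force(fr)
  expect_equal(m$grid[7, 16], 3)
  expect_equal(sum(m$grid), sum(fr$grid))
  expect_equal(mirror_force(m)$grid, fr$grid)
  sym <- force_frame(0, matrix(rep(1:16, each = 16), 16, 16)[, c(8:1, 1:8)] * 0 + 1,
                     "M19", "healthy")
  expect_equal(mirror_force(sym)$grid, sym$grid)
})

test_that("item features: healthy-identical recording yields unit ratios", {
  rec <- gen_recording(impairment_profile(noise_sd = 0, seed = 2))
  reg <- build_registry()
  for (id in c("5", "12", "20", "24", "26", "31", "32", "33")) {
    fe <- item_features(rec, reg[[id]])
    for (f in fe) {
      ins <- f$inputs
      for (nm in names(ins)) {
        if (nm == "sd") expect_lt(ins[[nm]], 1e-6)
        else expect_equal(unname(ins[[nm]]), 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("uninformative healthy reference is reported by name", {
  rec <- gen_recording(impairment_profile(noise_sd = 0, seed = 2))
  # zero out the healthy force frames of M16 -> hook-grasp denominator gone
  rec$force_frames <- lapply(rec$force_frames, function(f) {
    if (f$motion_id == "M16" && f$side == "healthy") f$grid[] <- 0
    f
  })
  reg <- build_registry()
  err <- tryCatch(item_features(rec, reg[["26"]]), error = identity)
  expect_s3_class(err, "autofma_uninformative_reference_error")
  expect_match(conditionMessage(err), "grip force sum")
})
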