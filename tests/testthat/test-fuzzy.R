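test_that("trapezoid membership matches the piecewise definition", {
  mf <- trapezoid_mf(0.1, 0.4, 0.6, 0.9)
  expect_equal(membership(mf, 0.5), 1)            # plateau
  expect_equal(membership(mf, 0.25), 0.5)         # (0.25-0.1)/(0.4-0.1)
  expect_equal(membership(mf, 0.1), 0)            # x = a
  expect_equal(membership(mf, 0.9), 0)            # x = d
  expect_equal(membership(mf, 0.75), 0.5)         # falling edge
  lo <- trapezoid_mf(-0.4, -0.1, 0.1, 0.4)
  expect_equal(membership(lo, 0), 1)
  expect_equal(membership(lo, 0.25), 0.5)
  # vectorised
  expect_equal(membership(mf, c(0, 0.5, 1)), c(0, 1, 0))
  # degenerate vertical edge behaves as a crisp step
  step <- trapezoid_mf(0, 0, 0.5, 1)
  expect_equal(membership(step, 0.25), 1)
  expect_error(trapezoid_mf(1, 0, 2, 3), class = "autofma_parameter_error")
})

test_that("triangle membership including degenerate shoulders", {
  mid <- triangle_mf(0, 1, 2)
  expect_equal(membership(mid, 1), 1)
  expect_equal(membership(mid, 0.5), 0.5)
  expect_equal(membership(mid, 2), 0)
  hi <- triangle_mf(1, 2, 2)
  expect_equal(membership(hi, 2), 1)              # right shoulder
  expect_equal(membership(hi, 1.5), 0.5)
  lo <- triangle_mf(0, 0, 1)
  expect_equal(membership(lo, 0), 1)
  expect_equal(membership(lo, 0.5), 0.5)
})

test_that("default rule base is complete, oriented and weakest-link", {
  # single increasing input: low/medium/high -> score levels 0/1/2
  r1 <- default_rule_base(1, "increasing")
  expect_equal(nrow(r1), 3)
  expect_equal(r1$output[match(c("low", "medium", "high"), r1$in1)],
               c("low", "medium", "high"))
  # decreasing input inverts the mapping
  r1d <- default_rule_base(1, "decreasing")
  expect_equal(r1d$output[match(c("low", "medium", "high"), r1d$in1)],
               c("high", "medium", "low"))
  # three inputs (ROM/MV increasing, deviation decreasing)
  r3 <- default_rule_base(3, c("increasing", "increasing", "decreasing"))
  expect_equal(nrow(r3), 27)
  expect_false(anyDuplicated(paste(r3$in1, r3$in2, r3$in3)) > 0)
  # all ratios high and deviation low -> high score
  expect_equal(r3$output[r3$in1 == "high" & r3$in2 == "high" & r3$in3 == "low"],
               "high")
  # any oriented-low input forces a low score
  expect_true(all(r3$output[r3$in1 == "low"] == "low"))
  expect_true(all(r3$output[r3$in3 == "high"] == "low"))
})

test_that("Mamdani inference reproduces analytic centroids", {
  f1 <- fis_spec("x", "increasing")
  # only "high" fires at full strength: centroid of the [1,2,2] triangle;
  # agreement is at the quadrature accuracy of the 2001-point grid
  r <- mamdani_score(f1, list(x = 1.0))
  expect_equal(r$crisp, 5 / 3, tolerance = 1e-6)
  expect_equal(discretise(r$crisp), 2L)
  # only "medium" fires: symmetric triangle about 1
  expect_equal(mamdani_score(f1, list(x = 0.5))$crisp, 1.0, tolerance = 1e-9)
  # equal low/high strengths are symmetric about 1
  f_sym <- fis_spec("x", "increasing",
                    input_mfs = list(low = trapezoid_mf(-1, -1, 0.2, 0.6),
                                     medium = trapezoid_mf(0.2, 0.45, 0.55, 0.8),
                                     high = trapezoid_mf(0.4, 0.8, 2, 2)))
  r2 <- mamdani_score(f_sym, list(x = 0.5))
  expect_equal(r2$activations[["low"]], r2$activations[["high"]])
  expect_equal(r2$crisp, 1.0, tolerance = 1e-9)
  # NaN input is an error; no rule fired -> midpoint with a flag
  expect_error(mamdani_score(f1, list(x = NaN)),
               class = "autofma_parameter_error")
})

test_that("crisp output is monotone (to the engine bound) and stays in range", {
  f3 <- fis_spec(c("rom_ratio", "mv_ratio", "sd"),
                 c("increasing", "increasing", "decreasing"))
  grid <- seq(0, 1.4, by = 0.05)
  for (others in list(c(0.2, 0.3), c(0.5, 0.5), c(1, 0.1))) {
    crisp <- vapply(grid, function(x) {
      mamdani_score(f3, list(rom_ratio = x, mv_ratio = others[1],
                             sd = others[2]))$crisp
    }, numeric(1))
    expect_true(all(diff(crisp) >= -0.06))      # centroid dip bound
    expect_true(all(diff(vapply(crisp, discretise, integer(1))) >= 0))
    crisp_sd <- vapply(grid, function(x) {
      mamdani_score(f3, list(rom_ratio = others[1], mv_ratio = others[2],
                             sd = x))$crisp
    }, numeric(1))
    expect_true(all(diff(crisp_sd) <= 0.06))
    # crisp output bounded by the centroids of the outer sets
    expect_true(all(crisp >= 1 / 3 - 1e-6 & crisp <= 5 / 3 + 1e-6))
  }
})

test_that("engine agrees with the brute-force oracle on random systems", {
  set.seed(1234)
  for (i in 1:25) {
    fis <- random_fis()
    for (rep in 1:3) {
      x <- as.list(runif(length(fis$input_names), -0.2, 1.6))
      names(x) <- fis$input_names
      expect_equal(mamdani_score(fis, x)$crisp, mamdani_oracle(fis, x),
                   tolerance = 1e-9)
    }
  }
})

test_that("discretisation rounds to the nearest score, half-points down", {
  expect_identical(discretise(1.667), 2L)
  expect_identical(discretise(0.5), 0L)
  expect_identical(discretise(1.5), 1L)
  expect_identical(discretise(1.0), 1L)
  expect_identical(discretise(0.51), 1L)
  expect_error(discretise(2.3), class = "autofma_parameter_error")
})

test_that("sub-score combination: worked examples and properties", {
  expect_identical(combine_subscores(c(1, 2, 1)), 1L)
  expect_identical(combine_subscores(c(2, 2, 2)), 2L)
  expect_identical(combine_subscores(c(0, 2, 2)), 0L)
  # permutation invariance and singleton idempotence
  set.seed(2)
  for (i in 1:10) {
    s <- sample(0:2, sample(1:4, 1), replace = TRUE)
    expect_identical(combine_subscores(s),
                     combine_subscores(s[sample.int(length(s))]))
  }
  for (v in 0:2) expect_identical(combine_subscores(v), as.integer(v))
  expect_error(combine_subscores(integer(0)), class = "autofma_parameter_error")
  expect_error(combine_subscores(c(1, 3)), class = "autofma_parameter_error")
})

test_that("FIS specifications survive a JSON config round-trip", {
  fis <- fis_spec(c("rom_ratio", "mv_ratio", "sd"),
                  c("increasing", "increasing", "decreasing"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fis_config(fis, path)
  back <- read_fis_config(path)
  expect_equal(back$input_names, fis$input_names)
  expect_equal(back$input_mfs, fis$input_mfs)
  expect_equal(back$output_mfs, fis$output_mfs)
  expect_equal(back$rules$output, fis$rules$output)
  x <- list(rom_ratio = 0.7, mv_ratio = 0.33, sd = 0.2)
  expect_equal(mamdani_score(back, x)$crisp, mamdani_score(fis, x)$crisp)
  # incomplete rule bases are rejected
  expect_error(fis_spec("x", rules = data.frame(in1 = "low", output = "low")),
               class = "autofma_config_error")
})
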