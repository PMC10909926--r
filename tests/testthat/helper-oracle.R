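# Independent brute-force Mamdani oracle: direct piecewise membership
# formulas, explicit rule loops, pointwise min/max on a dense grid, and
# centroid by pracma::trapz. Shares no code with the package engine beyond
# the documented contract (input saturation on the outer plateaus).

oracle_trap <- function(x, k) {
  a <- k[1]; b <- k[2]; cc <- k[3]; d <- k[4]
  if (x >= b && x <= cc) return(1)
  if (x > a && x < b) return((x - a) / (b - a))
  if (x > cc && x < d) return((d - x) / (d - cc))
  0
}

oracle_tri <- function(x, k) {
  e <- k[1]; f <- k[2]; g <- k[3]
  if (x == f) return(1)
  if (x > e && x < f) return((x - e) / (f - e))
  if (x > f && x < g) return((g - x) / (g - f))
  0
}

oracle_mf_eval <- function(mf, x) {
  if (inherits(mf, "trapezoid_mf")) {
    vapply(x, oracle_trap, numeric(1), k = c(mf$a, mf$b, mf$c, mf$d))
  } else {
    vapply(x, oracle_tri, numeric(1), k = c(mf$e, mf$f, mf$g))
  }
}

mamdani_oracle <- function(fis, inputs, n_grid = 2001) {
  lo <- fis$input_universe[1]; hi <- fis$input_universe[2]
  if (inherits(fis$input_mfs$low, "trapezoid_mf")) lo <- max(lo, fis$input_mfs$low$b)
  if (inherits(fis$input_mfs$high, "trapezoid_mf")) hi <- min(hi, fis$input_mfs$high$c)
  k <- length(fis$input_names)
  x <- numeric(k)
  for (j in seq_len(k)) {
    v <- inputs[[fis$input_names[j]]]
    x[j] <- min(max(v, lo), hi)
  }
  y <- seq(fis$output_universe[1], fis$output_universe[2], length.out = n_grid)
  agg <- rep(0, n_grid)
  for (r in seq_len(nrow(fis$rules))) {
    s <- Inf
    for (j in seq_len(k)) {
      lab <- fis$rules[r, paste0("in", j)]
      s <- min(s, oracle_mf_eval(fis$input_mfs[[lab]], x[j]))
    }
    if (s > 0) {
      out_mu <- oracle_mf_eval(fis$output_mfs[[fis$rules$output[r]]], y)
      agg <- pmax(agg, pmin(s, out_mu))
    }
  }
  if (max(agg) == 0) return(mean(fis$output_universe))
  pracma::trapz(y, y * agg) / pracma::trapz(y, agg)
}

# Random FIS with sorted random knots and a random complete rule base.
random_fis <- function(k = sample(1:3, 1)) {
  rand_trap <- function() do.call(trapezoid_mf, as.list(sort(runif(4, -0.4, 1.6))))
  rand_tri <- function() do.call(triangle_mf, as.list(sort(runif(3, 0, 2))))
  rules <- default_rule_base(k, rep("increasing", k))
  rules$output <- sample(c("low", "medium", "high"), nrow(rules), replace = TRUE)
  fis_spec(paste0("x", seq_len(k)),
           rep("increasing", k),
           input_universe = c(0, 1.4),
           input_mfs = list(low = rand_trap(), medium = rand_trap(),
                            high = rand_trap()),
           output_mfs = list(low = rand_tri(), medium = rand_tri(),
                             high = rand_tri()),
           rules = rules)
}
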