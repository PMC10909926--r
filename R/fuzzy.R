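## Mamdani fuzzy inference: trapezoid/triangle membership functions,
## complete 3^k rule bases with monotone "weakest link" construction,
## min-implication / max-aggregation, centroid defuzzification on a
## 2001-point uniform discretisation of the output universe.

#' Trapezoidal membership function
#'
#' Piecewise-linear fuzzy set with knots `a <= b <= c <= d`: zero outside
#' `(a, d)`, rising on `(a, b)`, one on `[b, c]`, falling on `(c, d)`.
#' Degenerate vertical edges (`b == a` or `d == c`) behave as crisp steps.
#'
#' @param a,b,c,d knots.
#' @return A `trapezoid_mf` object.
#' @export
trapezoid_mf <- function(a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    stop_autofma("trapezoid knots must satisfy a <= b <= c <= d",
                 class = "autofma_parameter_error")
  }
  structure(list(a = a, b = b, c = c, d = d), class = "trapezoid_mf")
}

#' Triangular membership function
#'
#' Knots `e <= f <= g`: zero outside `(e, g)`, peak 1 at `f`. Degenerate
#' shoulders (`e == f` or `f == g`) are right-angle triangles with
#' membership 1 at the shared knot.
#'
#' @param e,f,g knots.
#' @return A `triangle_mf` object.
#' @export
triangle_mf <- function(e, f, g) {
  if (!(e <= f && f <= g)) {
    stop_autofma("triangle knots must satisfy e <= f <= g",
                 class = "autofma_parameter_error")
  }
  structure(list(e = e, f = f, g = g), class = "triangle_mf")
}

#' Evaluate a membership function
#'
#' @param mf a [trapezoid_mf()] or [triangle_mf()].
#' @param x numeric vector of crisp values.
#' @return Membership grades in `[0, 1]`, vectorised over `x`.
#' @export
membership <- function(mf, x) UseMethod("membership")

#' @export
membership.trapezoid_mf <- function(mf, x) {
  y <- numeric(length(x))
  y[x >= mf$b & x <= mf$c] <- 1
  ris <- x > mf$a & x < mf$b
  y[ris] <- (x[ris] - mf$a) / (mf$b - mf$a)
  fal <- x > mf$c & x < mf$d
  y[fal] <- (mf$d - x[fal]) / (mf$d - mf$c)
  y
}

#' @export
membership.triangle_mf <- function(mf, x) {
  y <- numeric(length(x))
  y[x == mf$f] <- 1
  ris <- x > mf$e & x < mf$f
  y[ris] <- (x[ris] - mf$e) / (mf$f - mf$e)
  fal <- x > mf$f & x < mf$g
  y[fal] <- (mf$g - x[fal]) / (mf$g - mf$f)
  y
}

FUZZY_LEVELS <- c("low", "medium", "high")

#' Default input membership functions
#'
#' The three trapezoids used for every ratio/deviation input unless a
#' per-item configuration overrides them:
#' low `[-0.4, -0.1, 0.1, 0.4]`, medium `[0.1, 0.4, 0.6, 0.9]`,
#' high `[0.6, 0.9, 1.1, 1.4]` on the universe `[0, 1.4]`.
#'
#' @return Named list of three [trapezoid_mf()].
#' @export
default_input_mfs <- function() {
  list(low = trapezoid_mf(-0.4, -0.1, 0.1, 0.4),
       medium = trapezoid_mf(0.1, 0.4, 0.6, 0.9),
       high = trapezoid_mf(0.6, 0.9, 1.1, 1.4))
}

#' Default output membership functions
#'
#' Score triangles on the universe `[0, 2]`: low `[0, 0, 1]`,
#' medium `[0, 1, 2]`, high `[1, 2, 2]`.
#'
#' @return Named list of three [triangle_mf()].
#' @export
default_output_mfs <- function() {
  list(low = triangle_mf(0, 0, 1),
       medium = triangle_mf(0, 1, 2),
       high = triangle_mf(1, 2, 2))
}

#' Build the default complete rule base
#'
#' One rule per combination of input labels (a complete `3^k` base,
#' `k in {1, 2, 3}`). Each label is mapped to an oriented level
#' (low/medium/high -> 0/1/2 for increasing-direction inputs, inverted for
#' decreasing-direction inputs such as the side-to-side deviation), and the
#' output label is the element-wise minimum of the oriented levels - the
#' weakest input limits the score. The resulting inference is monotone by
#' construction.
#'
#' @param k number of inputs (1-3).
#' @param directions character vector of length `k`, each `"increasing"`
#'   or `"decreasing"`.
#' @return data.frame with columns `in1..ink` (input labels) and `output`.
#' @export
default_rule_base <- function(k, directions) {
  if (!k %in% 1:3) {
    stop_autofma("rule base supports 1-3 inputs, got %d", k,
                 class = "autofma_config_error")
  }
  if (length(directions) != k ||
      !all(directions %in% c("increasing", "decreasing"))) {
    stop_autofma("directions must be length-%d with values increasing/decreasing", k,
                 class = "autofma_config_error")
  }
  combos <- do.call(expand.grid,
                    c(rep(list(FUZZY_LEVELS), k),
                      list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  names(combos) <- paste0("in", seq_len(k))
  lev <- apply(combos, 1, function(row) {
    oriented <- vapply(seq_len(k), function(j) {
      l <- match(row[[j]], FUZZY_LEVELS) - 1L
      if (directions[j] == "decreasing") 2L - l else l
    }, integer(1))
    min(oriented)
  })
  combos$output <- FUZZY_LEVELS[lev + 1L]
  combos
}

#' Construct a fuzzy inference system specification
#'
#' @param input_names character vector naming the crisp inputs.
#' @param directions monotone direction of each input
#'   (`"increasing"` = larger is better).
#' @param input_universe common input universe (values are clipped to it).
#' @param input_mfs named list low/medium/high of [trapezoid_mf()].
#' @param output_mfs named list low/medium/high of [triangle_mf()].
#' @param output_universe output universe (score range).
#' @param rules rule base data.frame; defaults to [default_rule_base()].
#' @return A `fis_spec` object.
#' @export
fis_spec <- function(input_names,
                     directions = rep("increasing", length(input_names)),
                     input_universe = c(0, 1.4),
                     input_mfs = default_input_mfs(),
                     output_mfs = default_output_mfs(),
                     output_universe = c(0, 2),
                     rules = NULL) {
  k <- length(input_names)
  if (is.null(rules)) rules <- default_rule_base(k, directions)
  if (nrow(rules) != 3^k) {
    stop_autofma("rule base must cover all %d input combinations (got %d rows)",
                 3^k, nrow(rules), class = "autofma_config_error")
  }
  key <- do.call(paste, rules[paste0("in", seq_len(k))])
  if (anyDuplicated(key)) {
    stop_autofma("duplicate rules for the same input combination",
                 class = "autofma_config_error")
  }
  if (!all(rules$output %in% FUZZY_LEVELS)) {
    stop_autofma("rule outputs must be low/medium/high",
                 class = "autofma_config_error")
  }
  structure(list(input_names = input_names, directions = directions,
                 input_universe = input_universe,
                 input_mfs = input_mfs, output_mfs = output_mfs,
                 output_universe = output_universe, rules = rules),
            class = "fis_spec")
}

#' Run Mamdani inference for one input vector
#'
#' Rule firing strength is the minimum of the antecedent memberships
#' (Cartesian-product AND); implication clips each output set at the
#' strength (min), aggregation over rules is the pointwise maximum, and the
#' crisp score is the centroid of the aggregated set over a 2001-point
#' uniform discretisation of the output universe (trapezoid quadrature).
#'
#' @param fis a [fis_spec()].
#' @param inputs named numeric vector/list covering `fis$input_names`;
#'   values are clipped to the input universe.
#' @param n_grid discretisation points for defuzzification.
#' @return List with `crisp` (real in the output universe), `activations`
#'   (per output label aggregate strength) and `degenerate` (`TRUE` when no
#'   rule fired and the universe midpoint was returned).
#' @export
mamdani_score <- function(fis, inputs, n_grid = 2001) {
  ## Out-of-range values saturate on the outer membership plateaus: a ratio
  ## beyond the "high" core (affected better than healthy) keeps full "high"
  ## membership rather than falling into the zero-coverage sliver at the
  ## universe edge.
  lo_sat <- fis$input_universe[1]
  hi_sat <- fis$input_universe[2]
  if (inherits(fis$input_mfs$low, "trapezoid_mf")) {
    lo_sat <- max(lo_sat, fis$input_mfs$low$b)
  }
  if (inherits(fis$input_mfs$high, "trapezoid_mf")) {
    hi_sat <- min(hi_sat, fis$input_mfs$high$c)
  }
  x <- vapply(fis$input_names, function(nm) {
    v <- inputs[[nm]]
    if (is.null(v) || !is.finite(v)) {
      stop_autofma("FIS input '%s' missing or non-finite", nm,
                   class = "autofma_parameter_error")
    }
    min(max(v, lo_sat), hi_sat)
  }, numeric(1))
  k <- length(x)
  mu_in <- lapply(seq_len(k), function(j) {
    vapply(FUZZY_LEVELS, function(l) membership(fis$input_mfs[[l]], x[j]),
           numeric(1))
  })
  strength <- c(low = 0, medium = 0, high = 0)
  for (r in seq_len(nrow(fis$rules))) {
    s <- min(vapply(seq_len(k), function(j) {
      mu_in[[j]][[fis$rules[r, paste0("in", j)]]]
    }, numeric(1)))
    out <- fis$rules$output[r]
    strength[[out]] <- max(strength[[out]], s)
  }
  y <- seq(fis$output_universe[1], fis$output_universe[2], length.out = n_grid)
  mu <- rep(0, n_grid)
  for (l in FUZZY_LEVELS) {
    if (strength[[l]] > 0) {
      mu <- pmax(mu, pmin(strength[[l]], membership(fis$output_mfs[[l]], y)))
    }
  }
  w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
  denom <- sum(w * mu)
  if (denom <= 0) {
    return(list(crisp = mean(fis$output_universe), activations = strength,
                degenerate = TRUE))
  }
  list(crisp = sum(w * y * mu) / denom, activations = strength,
       degenerate = FALSE)
}

#' Discretise a crisp score to an integer item score
#'
#' Nearest integer in `{0, 1, 2}`; exact half-points round down
#' (conservative).
#'
#' @param crisp value in the output universe `[0, 2]`.
#' @return Integer 0, 1 or 2.
#' @export
discretise <- function(crisp) {
  if (!is.finite(crisp) || crisp < 0 || crisp > 2) {
    stop_autofma("crisp score %s outside [0, 2]", format(crisp),
                 class = "autofma_parameter_error")
  }
  if (crisp <= 0.5) 0L else if (crisp <= 1.5) 1L else 2L
}

#' Combine sub-motion scores into a final item score
#'
#' The multi-FIS combination rule: 0 if any sub-motion scored 0, 2 if all
#' scored 2, otherwise 1. Permutation-invariant and the identity on
#' singletons.
#'
#' @param scores integer vector of sub-motion scores in `{0, 1, 2}`.
#' @return Integer item score.
#' @export
combine_subscores <- function(scores) {
  if (length(scores) == 0) {
    stop_autofma("cannot combine an empty score list",
                 class = "autofma_parameter_error")
  }
  if (!all(scores %in% 0:2)) {
    stop_autofma("sub-scores must be integers in {0, 1, 2}",
                 class = "autofma_parameter_error")
  }
  if (any(scores == 0)) 0L else if (all(scores == 2)) 2L else 1L
}

mf_to_list <- function(mf) {
  if (inherits(mf, "trapezoid_mf")) {
    list(type = "trapezoid", knots = c(mf$a, mf$b, mf$c, mf$d))
  } else {
    list(type = "triangle", knots = c(mf$e, mf$f, mf$g))
  }
}

mf_from_list <- function(x) {
  k <- as.numeric(x$knots)
  if (x$type == "trapezoid") trapezoid_mf(k[1], k[2], k[3], k[4])
  else triangle_mf(k[1], k[2], k[3])
}

#' Serialise a FIS specification to a list (for JSON configuration)
#' @param fis a [fis_spec()].
#' @return Plain list mirroring the object's fields; see [fis_from_list()].
#' @export
fis_to_list <- function(fis) {
  list(input_names = fis$input_names, directions = fis$directions,
       input_universe = fis$input_universe,
       input_mfs = lapply(fis$input_mfs, mf_to_list),
       output_mfs = lapply(fis$output_mfs, mf_to_list),
       output_universe = fis$output_universe,
       rules = fis$rules)
}

#' Rebuild a FIS specification from its list form
#' @param x list produced by [fis_to_list()] (possibly via JSON).
#' @return A [fis_spec()].
#' @export
fis_from_list <- function(x) {
  rules <- x$rules
  if (!is.data.frame(rules)) {
    rules <- do.call(rbind, lapply(rules, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  fis_spec(unlist(x$input_names), unlist(x$directions),
           as.numeric(x$input_universe),
           lapply(x$input_mfs, mf_from_list),
           lapply(x$output_mfs, mf_from_list),
           as.numeric(x$output_universe),
           rules)
}

#' Write a FIS configuration file
#' @param fis a [fis_spec()].
#' @param path output JSON path.
#' @export
write_fis_config <- function(fis, path) {
  jsonlite::write_json(fis_to_list(fis), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read a FIS configuration file
#' @param path JSON file written by [write_fis_config()].
#' @return A [fis_spec()].
#' @export
read_fis_config <- function(path) {
  fis_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = TRUE))
}
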