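# B-spline least-squares fitting and greedy backward knot elimination.
# A knot vector is represented by its breakpoints (both data endpoints
# included); boundary knots carry multiplicity degree + 1 internally, so a
# cubic fit on b breakpoints has (b - 2) + 4 coefficients.

aug_knots <- function(breakpoints, degree) {
  c(rep(breakpoints[1], degree), breakpoints, rep(breakpoints[length(breakpoints)], degree))
}

check_breakpoints <- function(breakpoints) {
  if (length(breakpoints) < 2 || any(diff(breakpoints) <= 0))
    stop("breakpoints must be a strictly increasing vector of length >= 2")
  breakpoints
}

#' B-spline basis matrix
#'
#' Evaluates all B-spline basis functions of a given degree on the knot
#' vector defined by `breakpoints` (endpoints at multiplicity degree + 1).
#' The basis is non-negative and sums to one at every point of the domain.
#'
#' @param v Evaluation points; must lie within `[min(breakpoints), max(breakpoints)]`.
#' @param breakpoints Strictly increasing breakpoints including both
#'   domain endpoints.
#' @param degree Polynomial degree (default 3, cubic).
#' @return A `length(v)` x `(interior + degree + 1)` matrix of basis values.
#' @examples
#' rowSums(bspline_basis(seq(0, 5, 0.5), c(0, 1, 2.5, 5)))  # all 1
#' @export
bspline_basis <- function(v, breakpoints, degree = 3L) {
  check_breakpoints(breakpoints)
  if (any(v < breakpoints[1] | v > breakpoints[length(breakpoints)]))
    stop("bspline_basis: evaluation points outside the knot domain")
  splines::splineDesign(aug_knots(breakpoints, degree), v, ord = degree + 1L,
                        outer.ok = FALSE)
}

#' Initial uniform knot vector
#'
#' Builds the starting knot vector for backward elimination: both endpoints
#' plus interior knots at every `spacing` volts strictly inside the domain.
#' The default 0--5 V domain at 0.1 V spacing gives 51 knots (49 interior).
#'
#' @param v_min,v_max Domain endpoints.
#' @param spacing Interior knot spacing (> 0).
#' @return Numeric vector of breakpoints. If `spacing >= v_max - v_min`,
#'   only the endpoints.
#' @examples
#' length(initial_knot_vector(0, 5, 0.1))  # 51
#' @export
initial_knot_vector <- function(v_min = 0, v_max = 5, spacing = 0.1) {
  if (!(spacing > 0)) stop("initial_knot_vector: spacing must be > 0")
  if (!(v_max - v_min >= spacing)) return(c(v_min, v_max))
  n_int <- floor((v_max - v_min) / spacing - 1e-9)
  c(v_min, v_min + spacing * seq_len(n_int), v_max)
}

sweep_xy <- function(sweep) {
  if (inherits(sweep, "sensor_sweep")) list(x = sweep$heater_v, y = sweep$out_v)
  else if (is.list(sweep) && all(c("heater_v", "out_v") %in% names(sweep)))
    list(x = sweep$heater_v, y = sweep$out_v)
  else stop("expected a sensor_sweep or a list with heater_v and out_v")
}

# QR least squares of y on the basis over the given breakpoints; errors on
# rank deficiency, naming the first data-empty knot span.
fit_xy <- function(x, y, breakpoints, degree) {
  B <- bspline_basis(x, breakpoints, degree)
  if (length(y) < ncol(B))
    stop("fit_lsq_spline: need at least ", ncol(B), " data points, got ", length(y))
  z <- .lm.fit(B, y)
  if (z$rank < ncol(B)) {
    counts <- tabulate(findInterval(x, breakpoints, rightmost.closed = TRUE),
                       nbins = length(breakpoints) - 1)
    bad <- which(counts == 0)[1]
    span <- if (is.na(bad)) "unknown" else
      sprintf("(%.4g, %.4g)", breakpoints[bad], breakpoints[bad + 1])
    stop("fit_lsq_spline: rank-deficient design; empty knot span ", span)
  }
  coef <- numeric(ncol(B))
  coef[z$pivot] <- z$coefficients
  list(coefficients = coef, sse = sum(z$residuals^2))
}

#' Least-squares B-spline fit of a sweep
#'
#' Finds the control-point ordinates minimizing the sum of squared
#' residuals of the spline to the sweep's `(heater_v, out_v)` samples, for a
#' fixed knot vector. The coefficient count is always
#' `interior knots + degree + 1`.
#'
#' @param sweep A `sensor_sweep` (or list with `heater_v`, `out_v`).
#' @param breakpoints Knot vector including both endpoints.
#' @param degree Polynomial degree (default 3).
#' @return An object of class `bspline_fit` with fields `degree`,
#'   `breakpoints`, `coefficients` and `sse`.
#' @export
fit_lsq_spline <- function(sweep, breakpoints, degree = 3L) {
  xy <- sweep_xy(sweep)
  check_breakpoints(breakpoints)
  f <- fit_xy(xy$x, xy$y, breakpoints, degree)
  structure(list(degree = as.integer(degree), breakpoints = breakpoints,
                 coefficients = f$coefficients, sse = f$sse),
            class = "bspline_fit")
}

#' Evaluate a fitted B-spline
#'
#' @param fit A `bspline_fit`.
#' @param v Voltages at which to evaluate.
#' @return Fitted output voltages.
#' @export
predict_spline <- function(fit, v) {
  drop(bspline_basis(v, fit$breakpoints, fit$degree) %*% fit$coefficients)
}

#' @export
print.bspline_fit <- function(x, ...) {
  cat(sprintf("bspline_fit: degree %d, %d knots (%d interior), %d coefficients, sse %.4g\n",
              x$degree, length(x$breakpoints), length(x$breakpoints) - 2L,
              length(x$coefficients), x$sse))
  invisible(x)
}

#' Greedy backward knot elimination
#'
#' Starting from a (typically dense, uniform) knot vector, repeatedly
#' removes the interior knot whose deletion gives the smallest refit
#' sum-of-squares error, until the total knot count reaches `target_total`.
#' Removing a knot restricts the spline space to a subspace, so the error
#' sequence along the elimination path is non-decreasing. Ties are broken by
#' removing the leftmost candidate. Endpoints are never removable.
#'
#' With the default cubic degree, a 6-knot target yields the 8
#' control-point ordinates used as the network feature vector.
#'
#' @param sweep A `sensor_sweep` (or list with `heater_v`, `out_v`).
#' @param breakpoints Starting knot vector.
#' @param target_total Desired total knot count (endpoints included),
#'   between 2 and `length(breakpoints)`.
#' @param degree Polynomial degree (default 3).
#' @return A `bspline_fit` on the reduced knot vector, with an extra field
#'   `sse_path`: the error after the initial fit and after each removal.
#' @examples
#' s <- simulate_sweep(analyte_mix(0.1, 0.1), params = calibrate_amplitudes(),
#'                     noise_sd = 0)
#' fit <- eliminate_knots(s, initial_knot_vector(0, 5, 0.1), target_total = 6)
#' length(fit$coefficients)  # 8
#' @export
eliminate_knots <- function(sweep, breakpoints, target_total = 6L, degree = 3L) {
  xy <- sweep_xy(sweep)
  check_breakpoints(breakpoints)
  if (target_total < 2) stop("eliminate_knots: target_total must be >= 2")
  if (target_total > length(breakpoints))
    stop("eliminate_knots: target_total exceeds the starting knot count")
  bp <- breakpoints
  cur <- fit_xy(xy$x, xy$y, bp, degree)
  path <- cur$sse
  while (length(bp) > target_total) {
    interior <- seq(2L, length(bp) - 1L)
    sses <- vapply(interior, function(i) fit_xy(xy$x, xy$y, bp[-i], degree)$sse,
                   numeric(1))
    drop_i <- interior[which.min(sses)]  # which.min takes the leftmost tie
    bp <- bp[-drop_i]
    cur <- fit_xy(xy$x, xy$y, bp, degree)
    path <- c(path, cur$sse)
  }
  structure(list(degree = as.integer(degree), breakpoints = bp,
                 coefficients = cur$coefficients, sse = cur$sse,
                 sse_path = path),
            class = "bspline_fit")
}

#' Consensus knot elimination over several sweeps
#'
#' Variant of [eliminate_knots()] that selects one shared knot vector for a
#' whole calibration set: at each step the interior knot whose removal
#' minimizes the total (summed over sweeps) refit error is dropped. Useful
#' when a consistent feature space across sweeps is preferred over the
#' per-sweep optimum.
#'
#' @param sweeps List of sweeps.
#' @param breakpoints Starting knot vector.
#' @param target_total Desired total knot count.
#' @param degree Polynomial degree.
#' @return The reduced breakpoint vector.
#' @export
consensus_knots <- function(sweeps, breakpoints, target_total = 6L, degree = 3L) {
  check_breakpoints(breakpoints)
  if (target_total < 2) stop("consensus_knots: target_total must be >= 2")
  xys <- lapply(sweeps, sweep_xy)
  bp <- breakpoints
  total_sse <- function(b) sum(vapply(xys, function(d) fit_xy(d$x, d$y, b, degree)$sse,
                                      numeric(1)))
  while (length(bp) > target_total) {
    interior <- seq(2L, length(bp) - 1L)
    sses <- vapply(interior, function(i) total_sse(bp[-i]), numeric(1))
    bp <- bp[-interior[which.min(sses)]]
  }
  bp
}

#' Feature vector of a compressed sweep
#'
#' The eight control-point ordinates of the 6-knot cubic fit, in basis
#' order. These are the inputs of the quantification network.
#'
#' @param fit A `bspline_fit` with exactly 8 coefficients.
#' @return Numeric vector of length 8.
#' @export
sweep_features <- function(fit) {
  if (length(fit$coefficients) != 8L)
    stop("sweep_features: expected exactly 8 coefficients, got ",
         length(fit$coefficients))
  fit$coefficients
}

#' Compress a dataset of sweeps to a feature table
#'
#' Runs knot elimination on every sweep and assembles the feature table:
#' concentrations, the 8 spline features, the final fit error and the 6
#' retained knots. With `shared_knots = TRUE` a single consensus knot
#' vector is selected on the whole set first and every sweep is refit on it.
#'
#' @param sweeps List of `sensor_sweep` objects.
#' @param spacing Initial interior knot spacing in volts (default 0.1).
#' @param target_total Total knots to keep (default 6).
#' @param degree Polynomial degree (default 3).
#' @param shared_knots Use one consensus knot vector for all sweeps.
#' @return A data frame with columns `c_ethanol_pct`, `c_acetone_pct`,
#'   `replicate`, `f1`..`f8`, `sse`, `knot1`..`knot6` (knot columns named up
#'   to `target_total`).
#' @export
compress_dataset <- function(sweeps, spacing = 0.1, target_total = 6L,
                             degree = 3L, shared_knots = FALSE) {
  stopifnot(length(sweeps) >= 1)
  rng <- range(sweeps[[1]]$heater_v)
  start <- initial_knot_vector(rng[1], rng[2], spacing)
  shared <- if (shared_knots) consensus_knots(sweeps, start, target_total, degree)
  fits <- lapply(sweeps, function(s) {
    if (shared_knots) fit_lsq_spline(s, shared, degree)
    else eliminate_knots(s, start, target_total, degree)
  })
  p <- length(fits[[1]]$coefficients)
  feat <- t(vapply(fits, function(f) f$coefficients, numeric(p)))
  colnames(feat) <- paste0("f", seq_len(p))
  knots <- t(vapply(fits, function(f) f$breakpoints, numeric(target_total)))
  colnames(knots) <- paste0("knot", seq_len(target_total))
  cbind(
    data.frame(
      c_ethanol_pct = vapply(sweeps, function(s) s$mix$c_ethanol, numeric(1)),
      c_acetone_pct = vapply(sweeps, function(s) s$mix$c_acetone, numeric(1)),
      replicate = vapply(sweeps, function(s) s$replicate, integer(1))
    ),
    as.data.frame(feat),
    sse = vapply(fits, function(f) f$sse, numeric(1)),
    as.data.frame(knots)
  )
}
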