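#' Construct a piecewise profile parameter set
#'
#' The trajectory model used throughout the package is a continuous
#' plateau--ramp--plateau--ramp--plateau curve with seven free parameters:
#' four durations `t1..t4` (hours) and three amplitudes `A1..A3`
#' (dimensionless, on the normalized expression scale).  The origin `t0` is
#' fixed at the first sampling time and is not fitted.  The curve is flat at
#' `A1` for `t1` hours, ramps linearly to `A2` over `t2` hours, stays at `A2`
#' for `t3` hours, ramps linearly to `A3` over `t4` hours, and stays at `A3`
#' thereafter.  `t1` is the time to the first inflection; `t2 + t3 + t4` is
#' the time from the first inflection until the profile levels off.
#'
#' @param t1,t2,t3,t4 Segment durations in hours, each `>= 0`.
#' @param A1,A2,A3 Plateau amplitudes, each `>= 0`.
#' @param t0 Origin time in hours (first sample time).
#' @return An object of class `"piecewise_params"` (a named numeric vector
#'   with attribute `t0`).
#' @examples
#' p <- piecewise_params(t1 = 1, t2 = 2, t3 = 0, t4 = 4, A1 = 1, A2 = 0.2,
#'                       A3 = 0.6, t0 = 3)
#' evaluate_piecewise(p, c(3, 4, 5, 6, 8, 24))
#' @export
piecewise_params <- function(t1, t2, t3, t4, A1, A2, A3, t0 = 0) {
  th <- c(t1 = t1, t2 = t2, t3 = t3, t4 = t4, A1 = A1, A2 = A2, A3 = A3)
  if (any(!is.finite(th))) stop("piecewise parameters must be finite")
  if (any(th < 0)) stop("piecewise durations and amplitudes must be >= 0")
  structure(th, t0 = t0, class = "piecewise_params")
}

#' @export
print.piecewise_params <- function(x, ...) {
  cat("Piecewise profile (t0 =", attr(x, "t0"), "h):\n")
  print(unclass(x))
  invisible(x)
}

#' Evaluate the piecewise profile curve
#'
#' Evaluates the seven-parameter plateau/ramp curve at the requested times.
#' The curve is continuous in both `t` and the parameters; zero-duration
#' ramps degenerate to steps evaluated on the plateau side.
#'
#' @param params A [piecewise_params()] object, or a numeric vector with
#'   elements `t1,t2,t3,t4,A1,A2,A3` (in that order).
#' @param t Numeric vector of times (hours); all must be `>= t0`.
#' @param t0 Origin time; defaults to the `t0` attribute of `params` (or 0).
#' @return Numeric vector of curve values, one per element of `t`.
#' @export
evaluate_piecewise <- function(params, t, t0 = NULL) {
  th <- as.numeric(params)
  if (length(th) != 7L) stop("expected 7 parameters (t1..t4, A1..A3)")
  if (is.null(t0)) t0 <- attr(params, "t0")
  if (is.null(t0)) t0 <- 0
  if (any(t < t0 - 1e-12)) stop("evaluation times must be >= t0 = ", t0)
  k1 <- t0 + th[1L]
  k2 <- k1 + th[2L]
  k3 <- k2 + th[3L]
  k4 <- k3 + th[4L]
  s <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    s[i] <- if (ti <= k1) {
      th[5L]
    } else if (ti < k2) {
      th[5L] + (th[6L] - th[5L]) * (ti - k1) / th[2L]
    } else if (ti <= k3) {
      th[6L]
    } else if (ti < k4) {
      th[6L] + (th[7L] - th[6L]) * (ti - k3) / th[4L]
    } else {
      th[7L]
    }
  }
  s
}

#' Error-scaled cost of a candidate curve
#'
#' The fit criterion is the squared deviation between the fitted curve and
#' the replicate-averaged data, scaled point-wise by the replicate standard
#' deviation: `F = sum_j (d_j - s_j)^2 / sigma_j^2`.  Scaling by the SD
#' down-weights time points with larger replicate error.
#'
#' @param d Replicate-mean levels per time point.
#' @param s Fitted curve values at the same time points.
#' @param sigma Replicate standard deviations, all `> 0` (floor upstream with
#'   [average_replicates()]).
#' @return The scalar cost `F >= 0`; zero iff the curve interpolates `d`.
#' @export
profile_cost <- function(d, s, sigma) {
  if (length(d) != length(s) || length(d) != length(sigma))
    stop("d, s and sigma must have the same length")
  if (any(sigma <= 0)) stop("sigma must be strictly positive (apply a floor)")
  sum((d - s)^2 / sigma^2)
}
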