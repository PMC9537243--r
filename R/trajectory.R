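# Slow hemodynamic trajectory specifications for the simulator: the
# beat-to-beat "true" SBP/DBP/HR paths are built from these, then per-beat
# jitter is layered on top.

#' Trajectory specifications
#'
#' A trajectory describes how a slowly varying quantity (heart rate, SBP,
#' DBP) evolves over a simulated recording.  A bare number is accepted
#' wherever a trajectory is expected and is treated as constant.
#'
#' * `traj_constant(value)` — flat.
#' * `traj_ramp(from, to)` — linear from `from` at t = 0 to `to` at the end
#'   of the recording.
#' * `traj_sine(base, amplitude, period_s, phase)` — sinusoidal modulation
#'   around `base`.
#' * `traj_piecewise(t_frac, values, method)` — linear (or step)
#'   interpolation through knots placed at fractions `t_frac` of the
#'   recording duration; used to build ramp-and-step protocols.
#'
#' @param value,from,to,base,amplitude trajectory levels (units of the
#'   quantity described).
#' @param period_s oscillation period in seconds.
#' @param phase phase offset in radians.
#' @param t_frac knot positions as fractions of the duration, in `[0, 1]`.
#' @param values knot values, same length as `t_frac`.
#' @param method `"linear"` or `"constant"` (step) interpolation.
#' @return A `bp_trajectory` specification list.
#' @export
traj_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "bp_trajectory")
}

#' @rdname traj_constant
#' @export
traj_ramp <- function(from, to) {
  structure(list(type = "ramp", from = from, to = to), class = "bp_trajectory")
}

#' @rdname traj_constant
#' @export
traj_sine <- function(base, amplitude, period_s, phase = 0) {
  structure(list(type = "sine", base = base, amplitude = amplitude,
                 period_s = period_s, phase = phase), class = "bp_trajectory")
}

#' @rdname traj_constant
#' @export
traj_piecewise <- function(t_frac, values, method = c("linear", "constant")) {
  method <- match.arg(method)
  stopifnot(length(t_frac) == length(values), !is.unsorted(t_frac))
  structure(list(type = "piecewise", t_frac = t_frac, values = values,
                 method = method), class = "bp_trajectory")
}

#' Evaluate a trajectory at given times
#'
#' @param spec a trajectory from [traj_constant()] and friends, or a bare
#'   number (constant shorthand).
#' @param t times in seconds.
#' @param duration_s recording duration (anchors ramps and piecewise knots).
#' @return Numeric vector, `length(t)` values.
#' @export
eval_trajectory <- function(spec, t, duration_s) {
  if (is.numeric(spec) && length(spec) == 1L) {
    return(rep(spec, length(t)))
  }
  stopifnot(inherits(spec, "bp_trajectory"))
  switch(spec$type,
    constant = rep(spec$value, length(t)),
    ramp = spec$from + (spec$to - spec$from) * clamp(t / duration_s, 0, 1),
    sine = spec$base + spec$amplitude *
      sin(2 * pi * t / spec$period_s + spec$phase),
    piecewise = stats::approx(
      x = spec$t_frac * duration_s, y = spec$values, xout = t,
      method = spec$method, rule = 2, f = 1)$y,
    stop("unknown trajectory type: ", spec$type)
  )
}
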