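#' Stimulus protocols
#'
#' Constructors for the external inputs \eqn{h(x, t)} driving each
#' population.  All stimuli evaluate to a field (one value per grid
#' site) at a given time via [stimulus_field()].
#'
#' * `stim_zero()`: no input.
#' * `stim_ball_pulse(amplitude, center, radius_exponent, delta)`: a
#'   spatially localized rectangular pulse
#'   \eqn{A\,\Omega(p^r |x - a|_p)\,1_{[0,\delta]}(t)}.  With
#'   `radius_exponent = 0` the spatial factor is 1 everywhere, giving a
#'   spatially uniform pulse of level `amplitude` (this is how the
#'   inhibitory input at level \eqn{Q} is specified in the pulse
#'   experiments).
#' * `stim_ball_constant(amplitude, center, radius_exponent)`: the same
#'   spatial profile, constant in time.
#' * `stim_hysteresis(mode)`: the binocular two-peak stimulus in Monna
#'   coordinates,
#'   \deqn{\tilde h(x,t) = e^{-(30(0.5 - m(x)) - 0.5 t)^2} +
#'         e^{-(30(0.5 - m(x)) + 0.5 t)^2},}
#'   whose peaks drift apart at speed 1/60 in the Monna coordinate.
#'   `mode = "open"` uses \eqn{\tilde h} directly (peaks only separate);
#'   `mode = "return"` plays \eqn{\tilde h(x, t)} for \eqn{t \le 18},
#'   then the time-reversed \eqn{\tilde h(x, 36 - t)} for
#'   \eqn{18 < t \le 36} (peaks move back together), and vanishes for
#'   \eqn{t > 36}.
#'
#' @param amplitude pulse height (real; may be negative for inhibitory
#'   input).
#' @param center grid index of the ball center.
#' @param radius_exponent integer `r >= 0`; the ball is
#'   \eqn{a + p^r Z_p}.
#' @param delta pulse duration, `> 0`; the pulse is supported on
#'   \eqn{[0, \delta]}.
#' @param mode `"open"` or `"return"`.
#' @return A `wc_stimulus` object.
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_zero <- function() {
  structure(list(kind = "zero"), class = "wc_stimulus")
}

#' @rdname stimulus
#' @export
stim_ball_pulse <- function(amplitude, center, radius_exponent, delta) {
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be > 0")
  structure(list(kind = "pulse", amplitude = amplitude, center = center,
                 radius_exponent = radius_exponent, delta = delta),
            class = "wc_stimulus")
}

#' @rdname stimulus
#' @export
stim_ball_constant <- function(amplitude, center, radius_exponent) {
  structure(list(kind = "constant", amplitude = amplitude, center = center,
                 radius_exponent = radius_exponent),
            class = "wc_stimulus")
}

#' @rdname stimulus
#' @export
stim_hysteresis <- function(mode = c("open", "return")) {
  mode <- match.arg(mode)
  structure(list(kind = paste0("hysteresis_", mode)), class = "wc_stimulus")
}

#' @export
print.wc_stimulus <- function(x, ...) {
  cat("stimulus:", x$kind)
  if (x$kind == "pulse")
    cat(sprintf(" (amplitude %g on ball %d + p^%d Zp, t in [0, %g])",
                x$amplitude, x$center, x$radius_exponent, x$delta))
  if (x$kind == "constant")
    cat(sprintf(" (amplitude %g on ball %d + p^%d Zp)",
                x$amplitude, x$center, x$radius_exponent))
  cat("\n")
  invisible(x)
}

hysteresis_profile <- function(m, t) {
  exp(-(30 * (0.5 - m) - 0.5 * t)^2) + exp(-(30 * (0.5 - m) + 0.5 * t)^2)
}

#' Evaluate a stimulus as a field at time t
#'
#' @param stim a `wc_stimulus`.
#' @param grid a [padic_grid()].
#' @param t time (scalar).
#' @return Numeric vector of length `grid$size`.
#' @export
stimulus_field <- function(stim, grid, t) {
  stopifnot(inherits(stim, "wc_stimulus"), length(t) == 1L, is.finite(t))
  switch(stim$kind,
    zero = numeric(grid$size),
    pulse = {
      if (t < 0 || t > stim$delta) return(numeric(grid$size))
      stim$amplitude *
        ball_indicator(grid$indices, stim$center, stim$radius_exponent, grid)
    },
    constant = stim$amplitude *
      ball_indicator(grid$indices, stim$center, stim$radius_exponent, grid),
    hysteresis_open = hysteresis_profile(monna_map(grid$indices, grid), t),
    hysteresis_return = {
      m <- monna_map(grid$indices, grid)
      if (t <= 18) hysteresis_profile(m, t)
      else if (t <= 36) hysteresis_profile(m, 36 - t)
      else numeric(grid$size)
    },
    stop("unknown stimulus kind: ", stim$kind))
}
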