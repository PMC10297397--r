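#' Radial exponential coupling kernel
#'
#' The interaction kernels of the hierarchical model are radial,
#' decreasing functions of the p-adic norm:
#' \deqn{w(x) = b\,e^{\sigma} - b\,e^{\sigma |x|_p},}
#' so close neurons (small \eqn{|x|_p}, deep common ancestor) interact
#' strongly, while the interaction vanishes exactly at the maximal
#' distance \eqn{|x|_p = 1}.  The value at the origin is
#' \eqn{b (e^{\sigma} - 1) > 0}.
#'
#' @param b amplitude, `> 0` (dimensionless coupling strength).
#' @param sigma decay/shape parameter, `> 0`.
#' @return An object of class `radial_kernel`.
#' @examples
#' w <- radial_kernel(b = 1.5, sigma = 4)   # the E-to-E coupling of the
#' kernel_eval(w, 0, padic_grid(3, 6))      # pulse experiments: ~80.4
#' @export
radial_kernel <- function(b, sigma) {
  if (!is.finite(b) || b <= 0) stop("'b' must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  structure(list(b = b, sigma = sigma), class = "radial_kernel")
}

#' @export
print.radial_kernel <- function(x, ...) {
  cat(sprintf("radial kernel w(x) = b e^s - b e^{s|x|_p}, b = %g, sigma = %g\n",
              x$b, x$sigma))
  invisible(x)
}

#' Evaluate a radial kernel at grid points
#'
#' @param kernel a [radial_kernel()].
#' @param x grid index vector (the norm of the canonical representative
#'   is used).
#' @param grid a [padic_grid()].
#' @return Numeric vector of kernel values, nonnegative on the grid.
#' @export
kernel_eval <- function(kernel, x, grid) {
  stopifnot(inherits(kernel, "radial_kernel"))
  nrm <- padic_norm(check_index(x, grid), grid$p)
  kernel$b * exp(kernel$sigma) - kernel$b * exp(kernel$sigma * nrm)
}

#' Sample a kernel on the whole grid
#'
#' Returns the vector \eqn{w_i = w(i)}, \eqn{i \in G_l}, used as the
#' convolution kernel of the discretized system.
#'
#' @inheritParams kernel_eval
#' @return Numeric vector of length `grid$size`.
#' @export
discretize_kernel <- function(kernel, grid) {
  kernel_eval(kernel, grid$indices, grid)
}

#' Two-term logistic sigmoid
#'
#' The gain function of each population is the shifted logistic
#' \deqn{S(z) = \frac{1}{1 + e^{-v (z - \theta)}} - \frac{1}{1 +
#' e^{v\theta}},}
#' which satisfies \eqn{S(0) = 0} exactly, is strictly increasing, and is
#' bounded between \eqn{-1/(1 + e^{v\theta})} and
#' \eqn{1 - 1/(1 + e^{v\theta})}.
#'
#' @param v slope, `> 0`.
#' @param theta threshold (real).
#' @return An object of class `wc_sigmoid`.
#' @examples
#' s <- wc_sigmoid(v = 2.75, theta = 9)
#' sigmoid_eval(0, s)  # exactly 0
#' @export
wc_sigmoid <- function(v, theta) {
  if (!is.finite(v) || v <= 0) stop("'v' must be > 0")
  if (!is.finite(theta)) stop("'theta' must be finite")
  structure(list(v = v, theta = theta), class = "wc_sigmoid")
}

#' @export
print.wc_sigmoid <- function(x, ...) {
  cat(sprintf("sigmoid S(z) = logis(v(z - theta)) - logis(-v theta), v = %g, theta = %g\n",
              x$v, x$theta))
  invisible(x)
}

#' Evaluate the sigmoid
#'
#' Applied entrywise to activity fields.  Uses [stats::plogis()], which
#' is overflow-safe: the argument \eqn{v (z - \theta)} can reach the
#' hundreds when matrix-backed couplings are in play.
#'
#' @param z numeric vector.
#' @param s a [wc_sigmoid()].
#' @return Numeric vector of the same length as `z`.
#' @export
sigmoid_eval <- function(z, s) {
  stopifnot(inherits(s, "wc_sigmoid"))
  stats::plogis(s$v * (z - s$theta)) - stats::plogis(-s$v * s$theta)
}

#' Bounds of the sigmoid
#'
#' Returns the infimum, supremum and sup-norm of \eqn{S}:
#' lower \eqn{-1/(1+e^{v\theta})}, upper \eqn{1 - 1/(1+e^{v\theta})}.
#' The sup-norm enters the a-priori trajectory bound
#' \eqn{|E(x,t)| \le \|E_0\|_\infty + \tau \|S_E\|_\infty} that holds
#' when the refractory coefficients vanish.
#'
#' @param s a [wc_sigmoid()].
#' @return List with `lower`, `upper`, `sup_norm`.
#' @export
sigmoid_bounds <- function(s) {
  lo <- -stats::plogis(-s$v * s$theta)
  hi <- 1 + lo
  list(lower = lo, upper = hi, sup_norm = max(abs(lo), abs(hi)))
}
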