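#' Hierarchical Wilson-Cowan model
#'
#' Bundles everything the dynamics need: the grid, the time constant
#' \eqn{\tau}, the refractory coefficients \eqn{r_E, r_I}, the four
#' couplings \eqn{w_{EE}, w_{EI}, w_{IE}, w_{II}}, the two sigmoids and
#' the two external inputs.  The discretized system is
#' \deqn{\tau \dot E = -E + (1 - r_E E) \odot
#'   S_E(A_{EE} E - A_{EI} I + h_E(\cdot, t)),}
#' \deqn{\tau \dot I = -I + (1 - r_I I) \odot
#'   S_I(A_{IE} E - A_{II} I + h_I(\cdot, t)),}
#' where each \eqn{A_{AB}} is the Haar-weighted group convolution (for a
#' [radial_kernel()] coupling) or the Haar-weighted integral operator
#' (for a matrix or [kernel_matrix_approx()] coupling, as when a
#' connection-matrix kernel replaces the E-to-E term) and the sigmoids
#' act entrywise.
#'
#' Radial kernels are discretized and their FFTs cached at construction,
#' so the right-hand side costs a handful of length-\eqn{p^l} FFTs.
#'
#' @param grid a [padic_grid()].
#' @param tau time constant, `> 0`.
#' @param r_E,r_I refractory coefficients, `>= 0`.
#' @param w_EE,w_EI,w_IE,w_II couplings: each a [radial_kernel()], a
#'   numeric vector of length `p^l` (an arbitrary discrete convolution
#'   kernel), a numeric `p^l x p^l` matrix, or a
#'   [kernel_matrix_approx()].
#' @param S_E,S_I [wc_sigmoid()] gain functions.
#' @param h_E,h_I `wc_stimulus` external inputs (default none).
#' @return An object of class `wc_model`.
#' @export
wc_model <- function(grid, tau, r_E, r_I,
                     w_EE, w_EI, w_IE, w_II,
                     S_E, S_I,
                     h_E = stim_zero(), h_I = stim_zero()) {
  stopifnot(inherits(grid, "padic_grid"))
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be > 0")
  if (r_E < 0 || r_I < 0) stop("refractory coefficients must be >= 0")
  stopifnot(inherits(S_E, "wc_sigmoid"), inherits(S_I, "wc_sigmoid"),
            inherits(h_E, "wc_stimulus"), inherits(h_I, "wc_stimulus"))
  couplings <- lapply(list(EE = w_EE, EI = w_EI, IE = w_IE, II = w_II),
                      prepare_coupling, grid = grid)
  structure(
    list(grid = grid, tau = tau, r_E = r_E, r_I = r_I,
         couplings = couplings, S_E = S_E, S_I = S_I,
         h_E = h_E, h_I = h_I),
    class = "wc_model")
}

prepare_coupling <- function(w, grid) {
  if (inherits(w, "radial_kernel")) {
    vec <- discretize_kernel(w, grid)
    list(kind = "kernel", spec = w, vec = vec, fft = stats::fft(vec))
  } else if (is.numeric(w) && !is.matrix(w)) {
    if (length(w) != grid$size)
      stop("vector coupling must have length p^l of the model grid")
    if (any(!is.finite(w))) stop("non-finite entries in coupling vector")
    list(kind = "kernel", vec = w, fft = stats::fft(w))
  } else {
    if (inherits(w, "kernel_matrix_approx")) w <- w$values
    if (!is.matrix(w) || nrow(w) != grid$size || ncol(w) != grid$size)
      stop("matrix coupling must be p^l x p^l on the model grid")
    if (any(!is.finite(w))) stop("non-finite entries in coupling matrix")
    list(kind = "matrix", mat = w)
  }
}

#' @export
print.wc_model <- function(x, ...) {
  kinds <- vapply(x$couplings, `[[`, "", "kind")
  cat(sprintf("Wilson-Cowan model on G_l (p = %d, l = %d, %d sites)\n",
              x$grid$p, x$grid$l, x$grid$size))
  cat(sprintf("  tau = %g, r_E = %g, r_I = %g\n", x$tau, x$r_E, x$r_I))
  cat("  couplings:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n")
  cat("  stimuli: h_E =", x$h_E$kind, ", h_I =", x$h_I$kind, "\n")
  invisible(x)
}

apply_coupling <- function(cp, phi, phi_fft, grid) {
  if (cp$kind == "kernel") {
    grid$haar_weight *
      (Re(stats::fft(cp$fft * phi_fft, inverse = TRUE)) / grid$size)
  } else {
    grid$haar_weight * as.numeric(cp$mat %*% phi)
  }
}

#' Right-hand side of the discretized Wilson-Cowan system
#'
#' Returns the time derivatives (including the \eqn{1/\tau} factor) of
#' both populations at state `(E, I)` and time `t`.
#'
#' @param E,I numeric field vectors of length `grid$size`.
#' @param t time (scalar).
#' @param model a [wc_model()].
#' @return List with components `dE` and `dI`.
#' @export
wc_rhs <- function(E, I, t, model) {
  stopifnot(inherits(model, "wc_model"))
  grid <- model$grid
  if (length(E) != grid$size || length(I) != grid$size)
    stop("state fields must have length p^l")
  if (any(!is.finite(E)) || any(!is.finite(I)))
    stop("non-finite state passed to wc_rhs")
  cps <- model$couplings
  E_fft <- if (cps$EE$kind == "kernel" || cps$IE$kind == "kernel")
    stats::fft(E) else NULL
  I_fft <- if (cps$EI$kind == "kernel" || cps$II$kind == "kernel")
    stats::fft(I) else NULL
  u_E <- apply_coupling(cps$EE, E, E_fft, grid) -
         apply_coupling(cps$EI, I, I_fft, grid) +
         stimulus_field(model$h_E, grid, t)
  u_I <- apply_coupling(cps$IE, E, E_fft, grid) -
         apply_coupling(cps$II, I, I_fft, grid) +
         stimulus_field(model$h_I, grid, t)
  dE <- (-E + (1 - model$r_E * E) * sigmoid_eval(u_E, model$S_E)) / model$tau
  dI <- (-I + (1 - model$r_I * I) * sigmoid_eval(u_I, model$S_I)) / model$tau
  list(dE = dE, dI = dI)
}

#' Integrate the model with a fixed-step explicit scheme
#'
#' Deterministic fixed-step integration from the initial fields, using
#' [deSolve::ode()] with the classical 4th-order Runge-Kutta scheme
#' (default) or explicit Euler.  Every step is recorded.
#'
#' @param model a [wc_model()].
#' @param E0,I0 initial fields (default: rest, all zeros).
#' @param t_end final time, `>= dt`.
#' @param dt step size, `> 0` (default 0.05).
#' @param method `"rk4"` or `"euler"`.
#' @return A `wc_trajectory`: list with `times` (length `nt`), matrices
#'   `E` and `I` of dimension `nt x p^l` (rows = time points, columns =
#'   sites in integer order), the `grid`, `dt` and `method`.
#' @examples
#' g <- padic_grid(2, 2)
#' m <- wc_model(g, tau = 10, r_E = 0, r_I = 0,
#'               radial_kernel(1, 1), radial_kernel(1, 1),
#'               radial_kernel(1, 1), radial_kernel(1, 1),
#'               wc_sigmoid(1, 1), wc_sigmoid(1, 1))
#' tr <- wc_integrate(m, t_end = 1, dt = 0.1)
#' max(abs(tr$E))  # 0: rest is a fixed point without stimulus
#' @export
wc_integrate <- function(model, E0 = NULL, I0 = NULL, t_end, dt = 0.05,
                         method = c("rk4", "euler")) {
  stopifnot(inherits(model, "wc_model"))
  method <- match.arg(method)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.finite(t_end) || t_end < dt) stop("'t_end' must be >= dt")
  n <- model$grid$size
  if (is.null(E0)) E0 <- numeric(n)
  if (is.null(I0)) I0 <- numeric(n)
  if (length(E0) != n || length(I0) != n)
    stop("initial fields must have length p^l")
  times <- seq(0, t_end, by = dt)
  func <- function(t, y, parms) {
    d <- wc_rhs(y[seq_len(n)], y[n + seq_len(n)], t, model)
    list(c(d$dE, d$dI))
  }
  sol <- deSolve::ode(y = c(E0, I0), times = times, func = func,
                      parms = NULL, method = method)
  if (any(!is.finite(sol))) {
    bad <- which(apply(sol, 1L, function(r) any(!is.finite(r))))[1L]
    stop(sprintf("non-finite state encountered at time %g",
                 times[min(bad, length(times))]))
  }
  structure(
    list(times = times,
         E = unname(sol[, 1L + seq_len(n), drop = FALSE]),
         I = unname(sol[, 1L + n + seq_len(n), drop = FALSE]),
         grid = model$grid, dt = dt, method = method),
    class = "wc_trajectory")
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf("Wilson-Cowan trajectory: %d time points (dt = %g, %s), %d sites\n",
              length(x$times), x$dt, x$method, x$grid$size))
  cat(sprintf("  t in [%g, %g]; max |E| = %.4g, max |I| = %.4g\n",
              x$times[1L], x$times[length(x$times)],
              max(abs(x$E)), max(abs(x$I))))
  invisible(x)
}
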