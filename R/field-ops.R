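#' Haar-weighted cyclic group convolution on G_l
#'
#' A locally constant function at level \eqn{l} is a vector over the
#' \eqn{p^l} sites, and convolution over the compact group reduces to
#' \deqn{(w * \phi)_k = p^{-l} \sum_{i \in G_l} w_{(k - i) \bmod p^l}
#' \,\phi_i,}
#' i.e. a circular convolution of length \eqn{p^l} scaled by the Haar
#' quadrature weight.  Since \eqn{G_l} is cyclic, the sum is evaluated
#' with the FFT in \eqn{O(n \log n)}; the imaginary round-off is
#' discarded.
#'
#' @param w,phi numeric vectors of length `grid$size` (kernel and field).
#' @param grid a [padic_grid()].
#' @return Numeric vector of length `grid$size`.
#' @examples
#' g <- padic_grid(2, 1)
#' group_convolve(c(2, 4), c(1, 3), g)  # c(7, 5)
#' @export
group_convolve <- function(w, phi, grid) {
  n <- grid$size
  if (length(w) != n || length(phi) != n)
    stop("'w' and 'phi' must have length p^l of the grid")
  if (any(!is.finite(w)) || any(!is.finite(phi)))
    stop("non-finite values in convolution input")
  out <- Re(stats::fft(stats::fft(w) * stats::fft(phi), inverse = TRUE)) / n
  grid$haar_weight * out
}

#' Haar-weighted integral operator from a kernel matrix
#'
#' Applies a general (not necessarily translation-invariant) kernel
#' \eqn{K(x, y)} to a field:
#' \deqn{(K \phi)_i = p^{-l} \sum_j K_{ij} \phi_j,}
#' the quadrature discretization of \eqn{\int K(x, y) \phi(y)\,dy}.
#' When `K` is the circulant matrix of a kernel vector this coincides
#' with [group_convolve()].
#'
#' @param K numeric `p^l x p^l` matrix (or a [kernel_matrix_approx()]
#'   whose `values` are used).
#' @param phi numeric field vector.
#' @param grid a [padic_grid()].
#' @return Numeric vector of length `grid$size`.
#' @export
integral_operator <- function(K, phi, grid) {
  if (inherits(K, "kernel_matrix_approx")) K <- K$values
  n <- grid$size
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("'K' must be a p^l x p^l matrix on the grid")
  if (length(phi) != n) stop("'phi' must have length p^l")
  grid$haar_weight * as.numeric(K %*% phi)
}

#' Circulant matrix of a kernel vector
#'
#' Builds the matrix \eqn{K_{ij} = w_{(i - j) \bmod p^l}} so that
#' [integral_operator()] with `K` reproduces [group_convolve()] with
#' `w`.  Mainly used to cross-check the two coupling code paths.
#'
#' @param w numeric kernel vector of length `grid$size`.
#' @param grid a [padic_grid()].
#' @return A `p^l x p^l` matrix.
#' @export
circulant_matrix <- function(w, grid) {
  n <- grid$size
  if (length(w) != n) stop("'w' must have length p^l")
  idx <- outer(0:(n - 1L), 0:(n - 1L), function(i, j) (i - j) %% n)
  matrix(w[idx + 1L], n, n)
}

#' Haar quadrature of a field
#'
#' The integral of a locally constant function over the unit ball is the
#' equal-weight quadrature \eqn{\int \phi\,dx = p^{-l} \sum_i \phi_i},
#' computed as a single sum divided once by \eqn{p^l} so that the mass
#' of the constant field 1 is exactly 1 and the mass of a ball indicator
#' of radius \eqn{p^{-r}} is exactly \eqn{p^{l-r}/p^l}.
#'
#' @param phi numeric field vector of length `grid$size`.
#' @param grid a [padic_grid()].
#' @return The Haar integral (scalar).
#' @examples
#' g <- padic_grid(3, 6)
#' haar_integral(rep(1, g$size), g)  # exactly 1
#' @export
haar_integral <- function(phi, grid) {
  if (length(phi) != grid$size) stop("'phi' must have length p^l")
  sum(phi) / grid$size
}

#' Project a field to a coarser level
#'
#' The projection \eqn{P_l} samples a level-\eqn{l'} field at the
#' canonical representatives \eqn{0, \dots, p^l - 1} of the coarser
#' grid: the resulting step function takes at each coarse ball the value
#' of the fine field at the ball's representative.  The sup-norm never
#' increases, and projecting an embedded field recovers it exactly.
#'
#' @param f numeric field vector at level `fine$l`.
#' @param fine,coarse [padic_grid()] objects with the same `p` and
#'   `coarse$l < fine$l`.
#' @return Numeric vector of length `coarse$size`.
#' @export
coarse_project <- function(f, fine, coarse) {
  if (fine$p != coarse$p) stop("grids must share the same prime p")
  if (coarse$l >= fine$l) stop("target level must be strictly coarser")
  if (length(f) != fine$size) stop("'f' must have length p^l of the fine grid")
  f[coarse$indices + 1L]
}

#' Embed a field into a finer level
#'
#' A level-\eqn{l} step function is unchanged as a function on
#' \eqn{\mathbb{Z}_p} when viewed at level \eqn{l' > l}: the fine site
#' \eqn{j} takes the value of the coarse site \eqn{j \bmod p^l}.  The
#' Haar integral is preserved.
#'
#' @param f numeric field vector at level `coarse$l`.
#' @param coarse,fine [padic_grid()] objects with the same `p` and
#'   `fine$l > coarse$l`.
#' @return Numeric vector of length `fine$size`.
#' @export
refine_embed <- function(f, coarse, fine) {
  if (fine$p != coarse$p) stop("grids must share the same prime p")
  if (fine$l <= coarse$l) stop("target level must be strictly finer")
  if (length(f) != coarse$size)
    stop("'f' must have length p^l of the coarse grid")
  f[(fine$indices %% coarse$size) + 1L]
}
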