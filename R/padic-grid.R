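#' The finite p-adic grid G_l
#'
#' Constructs the finite additive group \eqn{G_l = \mathbb{Z}_p / p^l
#' \mathbb{Z}_p}, identified with the integers \eqn{0, \dots, p^l - 1}
#' written in base \eqn{p}.  The grid carries the restriction of the p-adic
#' norm, so it is a finite ultrametric space whose points are the \eqn{p^l}
#' leaves of a rooted p-ary tree with \eqn{l + 1} levels.  The normalized
#' Haar measure of the unit ball assigns weight \eqn{p^{-l}} to each leaf,
#' which is the quadrature weight used everywhere in the package.
#'
#' @param p prime number, the branching factor of the tree.
#' @param l positive integer, the truncation level (tree depth).
#'
#' @return An object of class `padic_grid` with components `p`, `l`,
#'   `size` (\eqn{p^l}), `haar_weight` (\eqn{p^{-l}}), and `indices`
#'   (the canonical representatives `0:(size - 1)`).
#'
#' @examples
#' g <- padic_grid(3, 2)
#' g$size          # 9
#' g$haar_weight   # 1/9
#' @export
padic_grid <- function(p, l) {
  if (length(p) != 1L || !is.finite(p) || p != round(p) || !is_prime(p))
    stop("'p' must be a single prime number")
  if (length(l) != 1L || !is.finite(l) || l != round(l) || l < 1)
    stop("'l' must be a single integer >= 1")
  p <- as.integer(p)
  l <- as.integer(l)
  size <- p^l
  if (size > 2^30) stop("grid size p^l too large")
  structure(
    list(p = p, l = l, size = as.integer(size),
         haar_weight = p^(-l), indices = 0:(size - 1L)),
    class = "padic_grid")
}

#' @export
print.padic_grid <- function(x, ...) {
  cat(sprintf("p-adic grid G_l: p = %d, l = %d, %d sites, Haar weight %.6g\n",
              x$p, x$l, x$size, x$haar_weight))
  invisible(x)
}

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

check_index <- function(i, grid) {
  if (any(!is.finite(i)) || any(i != round(i)) ||
      any(i < 0) || any(i >= grid$size))
    stop("grid index out of range [0, p^l)")
  as.integer(i)
}

#' Base-p digit expansion of a grid index
#'
#' Every \eqn{i \in G_l} has a unique expansion
#' \eqn{i = i_0 + i_1 p + \dots + i_{l-1} p^{l-1}} with digits in
#' \eqn{\{0, \dots, p-1\}}; this returns the digit vector
#' \eqn{(i_0, \dots, i_{l-1})}.
#'
#' @param i grid index (scalar, `0 <= i < p^l`).
#' @param grid a [padic_grid()].
#' @return Integer vector of length `grid$l`.
#' @examples
#' padic_digits(5, padic_grid(3, 2))  # c(2, 1): 5 = 2 + 1*3
#' @export
padic_digits <- function(i, grid) {
  i <- check_index(i, grid)
  if (length(i) != 1L) stop("'i' must be a single index")
  d <- integer(grid$l)
  for (j in seq_len(grid$l)) {
    d[j] <- i %% grid$p
    i <- i %/% grid$p
  }
  d
}

#' Integer from base-p digits
#'
#' Inverse of [padic_digits()]: reassembles \eqn{\sum_j i_j p^j}.
#'
#' @param digits integer vector of base-p digits, least significant first.
#' @param p prime base.
#' @return The integer representative.
#' @export
padic_from_digits <- function(digits, p) {
  if (any(digits < 0 | digits >= p)) stop("digits must lie in 0..p-1")
  sum(digits * p^(seq_along(digits) - 1L))
}

#' p-adic valuation and norm
#'
#' The p-adic norm of an integer \eqn{x} is \eqn{|x|_p = p^{-v}} where
#' \eqn{v} is the multiplicity of \eqn{p} in \eqn{x}, and \eqn{|0|_p = 0}.
#' It satisfies the strong (ultrametric) triangle inequality
#' \eqn{|x + y|_p \le \max(|x|_p, |y|_p)}.  Vectorized over `i`.
#'
#' @param i integer vector.
#' @param p prime.
#' @return `padic_norm`: numeric vector of norms; `padic_valuation`:
#'   integer vector of multiplicities (`Inf` for 0).
#' @examples
#' padic_norm(c(0, 4, 6), 2)  # 0, 1/4, 1/2
#' @export
padic_norm <- function(i, p) {
  p^(-padic_valuation(i, p))
}

#' @rdname padic_norm
#' @export
padic_valuation <- function(i, p) {
  if (any(i != round(i))) stop("'i' must be integer-valued")
  v <- numeric(length(i))
  x <- abs(i)
  v[x == 0] <- Inf
  active <- which(x != 0)
  while (length(active)) {
    divisible <- active[x[active] %% p == 0]
    if (!length(divisible)) break
    v[divisible] <- v[divisible] + 1
    x[divisible] <- x[divisible] %/% p
    active <- divisible
  }
  v
}

#' Group operations on G_l
#'
#' `group_add` and `group_sub` are addition and subtraction modulo
#' \eqn{p^l}; they make the set of indices an abelian group (the cyclic
#' group of order \eqn{p^l}).  Vectorized with recycling.
#'
#' @param i,j grid indices.
#' @param grid a [padic_grid()].
#' @return Grid index vector.
#' @export
group_sub <- function(i, j, grid) {
  i <- check_index(i, grid); j <- check_index(j, grid)
  (i - j) %% grid$size
}

#' @rdname group_sub
#' @export
group_add <- function(i, j, grid) {
  i <- check_index(i, grid); j <- check_index(j, grid)
  (i + j) %% grid$size
}

#' Ultrametric distance between grid points
#'
#' \eqn{d(i, j) = |i - j|_p} computed on the canonical representative of
#' \eqn{(i - j) \bmod p^l}.  \eqn{-\log_p d(i,j)} is the depth of the
#' first common ancestor of the two leaves in the rooted tree.
#'
#' @inheritParams group_sub
#' @return Numeric vector of distances in \eqn{\{0\} \cup \{p^{-v}\}}.
#' @export
ultrametric_distance <- function(i, j, grid) {
  padic_norm(group_sub(i, j, grid), grid$p)
}

#' Ball membership indicator
#'
#' The ball \eqn{B_{-r}(a) = a + p^r \mathbb{Z}_p} has radius
#' \eqn{p^{-r}}; its characteristic function is
#' \eqn{\Omega(p^r |x - a|_p)}, equal to 1 exactly when
#' \eqn{x \equiv a \pmod{p^r}}.  On the grid a ball of radius
#' \eqn{p^{-r}} contains exactly \eqn{p^{l-r}} sites, so its Haar
#' measure is \eqn{p^{-r}}.  With `radius_exponent = 0` the ball is the
#' whole space and the indicator is identically 1.
#'
#' @param x grid index vector to test.
#' @param center grid index, the ball center \eqn{a}.
#' @param radius_exponent integer \eqn{r} with \eqn{0 \le r \le l}.
#' @param grid a [padic_grid()].
#' @return Numeric vector of 0/1 values.
#' @examples
#' g <- padic_grid(3, 3)
#' ball_indicator(13, 4, 2, g)  # 1: 13 = 4 + 9
#' @export
ball_indicator <- function(x, center, radius_exponent, grid) {
  if (length(radius_exponent) != 1L || radius_exponent != round(radius_exponent) ||
      radius_exponent < 0 || radius_exponent > grid$l)
    stop("'radius_exponent' must be an integer in 0..l")
  x <- check_index(x, grid)
  center <- check_index(center, grid)
  pr <- grid$p^radius_exponent
  as.numeric((x - center) %% pr == 0)
}

#' Monna map: digit-reversal embedding of G_l into [0, 1)
#'
#' \eqn{m(\sum_j i_j p^j) = \sum_j i_j p^{-(j+1)}}.  The map is injective
#' on the grid, sends 0 to 0, and sends every p-adic ball to a set of
#' points lying in a single subinterval of length \eqn{p^{-r}}, which is
#' why the package uses it to order heat-map axes.  Vectorized over `i`.
#'
#' @param i grid index vector.
#' @param grid a [padic_grid()].
#' @return Numeric vector of values in `[0, 1)`.
#' @examples
#' monna_map(0:3, padic_grid(2, 2))  # 0, 1/2, 1/4, 3/4
#' @export
monna_map <- function(i, grid) {
  i <- check_index(i, grid)
  m <- numeric(length(i))
  scale <- grid$p
  for (j in seq_len(grid$l)) {
    m <- m + (i %% grid$p) / scale
    i <- i %/% grid$p
    scale <- scale * grid$p
  }
  m
}

#' Reduction modulo p^r
#'
#' Truncates the base-p expansion of an index to its first `r` digits,
#' i.e. computes \eqn{i \bmod p^r}.  `r = l` is the identity and
#' `r = 0` sends everything to 0.  This is the reduction map used to
#' build block decompositions of connection matrices.
#'
#' @param i grid index vector.
#' @param r integer, target level with \eqn{0 \le r \le l}.
#' @param grid a [padic_grid()].
#' @return Index vector in `0:(p^r - 1)`.
#' @export
reduce_mod <- function(i, r, grid) {
  if (length(r) != 1L || r != round(r) || r < 0 || r > grid$l)
    stop("'r' must be an integer in 0..l")
  i <- check_index(i, grid)
  i %% as.integer(grid$p^r)
}

#' Tree (Monna) ordering of the grid
#'
#' Returns the permutation of `0:(p^l - 1)` that sorts indices by Monna
#' value.  Under this ordering every ball \eqn{\{x : x \equiv a \bmod
#' p^r\}} occupies a contiguous run of \eqn{p^{l-r}} positions, so heat
#' maps and matrices displayed in tree order show balls as contiguous
#' bands and blocks.  The Monna map is injective, hence the permutation
#' is unique and deterministic.
#'
#' @param grid a [padic_grid()].
#' @return Integer vector: the grid indices (0-based) in tree order.
#' @examples
#' tree_order(padic_grid(2, 2))  # 0 2 1 3
#' @export
tree_order <- function(grid) {
  grid$indices[order(monna_map(grid$indices, grid))]
}
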