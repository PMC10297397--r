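#' Pad a connection matrix to p-power size
#'
#' Embeds an \eqn{n \times n} connectivity matrix into the top-left
#' corner of a \eqn{p^k \times p^k} matrix filled with zeros, where
#' \eqn{k} is the smallest integer with \eqn{p^k \ge n}.  Row/column
#' indices of the padded matrix are then read as elements of \eqn{G_k}.
#'
#' @param A square numeric matrix (directed weights; orientation is
#'   preserved, no symmetrization).
#' @param p prime.
#' @return List with `values` (the padded matrix), `k`, `p`, and `n`
#'   (the original size).
#' @export
pad_matrix <- function(A, p) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("'A' must be a square matrix")
  if (any(!is.finite(A))) stop("'A' must have finite entries")
  if (!is_prime(p)) stop("'p' must be prime")
  n <- nrow(A)
  k <- 0L
  while (p^k < n) k <- k + 1L
  m <- p^k
  out <- matrix(0, m, m)
  out[seq_len(n), seq_len(n)] <- A
  dimnames(out) <- NULL
  list(values = out, k = k, p = as.integer(p), n = n)
}

#' Block decomposition induced by reduction mod p^r
#'
#' The reduction map sends an index to its first `r` base-p digits, and
#' its fibers split the \eqn{p^k \times p^k} index set into
#' \eqn{p^{2r}} blocks: block \eqn{(a, b)} collects the entries with row
#' \eqn{\equiv a} and column \eqn{\equiv b \pmod{p^r}}, i.e. rows in
#' the ball \eqn{a + p^r Z_p} and columns in \eqn{b + p^r Z_p}.  Each
#' block has \eqn{p^{2(k - r)}} entries and the blocks partition the
#' matrix.
#'
#' @param k level of the padded matrix.
#' @param r resolution, `0 <= r <= k`.
#' @param p prime.
#' @return Named list, one element per block `"a,b"`, each a two-column
#'   integer matrix of 0-based `(i, j)` index pairs.
#' @export
block_partition <- function(k, r, p) {
  if (r != round(r) || r < 0 || r > k) stop("'r' must be an integer in 0..k")
  n <- p^k; pr <- p^r
  idx <- 0:(n - 1L)
  blocks <- vector("list", pr * pr)
  names(blocks) <- as.vector(outer(0:(pr - 1L), 0:(pr - 1L),
                                   function(a, b) paste(a, b, sep = ",")))
  rows_by_res <- split(idx, idx %% pr)
  for (a in 0:(pr - 1L)) for (b in 0:(pr - 1L)) {
    ri <- rows_by_res[[as.character(a)]]
    ci <- rows_by_res[[as.character(b)]]
    blocks[[paste(a, b, sep = ",")]] <-
      cbind(i = rep(ri, times = length(ci)),
            j = rep(ci, each = length(ri)))
  }
  blocks
}

#' Locally translation-invariant kernel approximation of a matrix
#'
#' Approximates a \eqn{p^k \times p^k} matrix by a kernel
#' \eqn{K_r(x, y)} that is translation invariant within each pair of
#' balls of radius \eqn{p^{-r}}: inside block \eqn{(a, b)} the entry at
#' \eqn{(i, j)} may depend only on the group difference
#' \eqn{(i - j) \bmod p^k}.  Each difference class within a block is
#' replaced by its arithmetic mean, which is the mean-square orthogonal
#' projection onto such kernels; it preserves every block sum, is
#' idempotent, and reproduces the input exactly at `r = k`.  A circulant
#' input is a fixed point at every `r`.
#'
#' @param A_padded numeric `p^k x p^k` matrix (see [pad_matrix()]).
#' @param p prime.
#' @param k level (`nrow(A_padded)` must equal `p^k`).
#' @param r resolution, `0 <= r <= k`.
#' @return An object of class `kernel_matrix_approx`: list with
#'   `values` (the approximated matrix), `p`, `k`, `r`, and
#'   `block_profiles` (per-block difference profiles \eqn{\psi_{a,b}},
#'   a named list mapping difference class to mean value).
#' @examples
#' local_circulant_average(matrix(c(1, 5, 3, 7), 2, 2), p = 2, k = 1, r = 0)
#' @export
local_circulant_average <- function(A_padded, p, k, r) {
  n <- p^k
  if (!is.matrix(A_padded) || nrow(A_padded) != n || ncol(A_padded) != n)
    stop("'A_padded' must be a p^k x p^k matrix")
  if (r != round(r) || r < 0 || r > k) stop("'r' must be an integer in 0..k")
  pr <- p^r
  i <- rep(0:(n - 1L), times = n)          # row index, column-major
  j <- rep(0:(n - 1L), each = n)
  d <- (i - j) %% n
  key <- paste(i %% pr, j %% pr, d, sep = ";")
  means <- stats::ave(as.vector(A_padded), key, FUN = mean)
  K <- matrix(means, n, n)
  profiles <- tapply(as.vector(A_padded), key, mean)
  structure(
    list(values = K, p = as.integer(p), k = as.integer(k), r = as.integer(r),
         block_profiles = profiles),
    class = "kernel_matrix_approx")
}

#' @export
print.kernel_matrix_approx <- function(x, ...) {
  cat(sprintf(
    "locally translation-invariant kernel K_r: p = %d, k = %d, r = %d (%d x %d)\n",
    x$p, x$k, x$r, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Approximation error of a kernel matrix
#'
#' Entrywise discrepancy between a padded matrix and its
#' resolution-\eqn{r} kernel approximation.  Because the approximations
#' are nested orthogonal projections, the mean-square error is
#' nonincreasing in \eqn{r} and vanishes at \eqn{r = k}.
#'
#' @param A_padded numeric matrix.
#' @param K a [kernel_matrix_approx()] or matrix of the same shape.
#' @return List with `max_abs` and `mean_square`.
#' @export
approximation_error <- function(A_padded, K) {
  if (inherits(K, "kernel_matrix_approx")) K <- K$values
  if (!all(dim(A_padded) == dim(K))) stop("shape mismatch")
  d <- A_padded - K
  list(max_abs = max(abs(d)), mean_square = mean(d^2))
}

#' Synthetic hierarchical connection matrix
#'
#' Generates a stand-in for an empirical cortical connection matrix with
#' ultrametric structure: the weight between distinct nodes \eqn{i, j}
#' decays exponentially with their tree distance,
#' \deqn{a_{ij} = A\, e^{-\mathrm{decay}\,(k - v)} + \varepsilon_{ij},}
#' where \eqn{v = \mathrm{ord}_p((i - j) \bmod p^k)} is the depth of the
#' first common ancestor of the two leaves (so \eqn{k - v} counts the
#' levels separating them), \eqn{A} is the `amplitude`, and
#' \eqn{\varepsilon_{ij}} is independent Gaussian noise of standard
#' deviation `noise_sd`.  Entries are truncated at 0 and the diagonal is
#' set to 0.  With `noise_sd = 0` the matrix is circulant with respect
#' to subtraction mod \eqn{p^k}, hence reproduced exactly by
#' [local_circulant_average()] at every resolution.  The default
#' amplitude 3 mimics the ordinal 0-3 weight scale of published cortical
#' connectivity matrices.
#'
#' @param p prime.
#' @param k level; the matrix is `p^k x p^k`.
#' @param decay per-level decay rate, `> 0`.
#' @param noise_sd Gaussian noise standard deviation, `>= 0`.
#' @param seed integer seed; the generator is deterministic given the
#'   seed and restores the caller's RNG state.
#' @param amplitude weight of the closest (sibling-leaf) connections.
#' @return Numeric `p^k x p^k` matrix.
#' @export
synthetic_hierarchical_matrix <- function(p, k, decay = 1, noise_sd = 0.1,
                                          seed = 1L, amplitude = 3) {
  if (!is_prime(p)) stop("'p' must be prime")
  if (decay <= 0) stop("'decay' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  n <- p^k
  i <- rep(0:(n - 1L), times = n)
  j <- rep(0:(n - 1L), each = n)
  v <- padic_valuation((i - j) %% n, p)
  base <- amplitude * exp(-decay * (k - pmin(v, k)))
  A <- matrix(base, n, n)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
    A <- A + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
  }
  A <- pmax(A, 0)
  diag(A) <- 0
  A
}

#' Read or write a connection matrix as delimited text
#'
#' `read_connection_matrix()` accepts comma- or tab-separated square
#' numeric matrices, with an optional header row of node labels;
#' `write_connection_matrix()` writes at 15 significant digits so a
#' round trip is lossless to that precision.
#'
#' @param path file path.
#' @param A numeric matrix to write (optionally with `dimnames`).
#' @param labels optional character vector of node names.
#' @param sep field separator; inferred from content on read (`","` or
#'   tab), `","` on write by default.
#' @return `read_connection_matrix()`: numeric matrix, with column names
#'   when a header is present.
#' @export
read_connection_matrix <- function(path, sep = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  if (is.null(sep)) sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "\t"
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows in %s: row %d has %d fields, expected %d",
                 path, which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                 widths[1L]))
  labels <- NULL
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  if (anyNA(first)) {  # header row of labels
    labels <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (!length(cells)) stop("matrix file contains only a header: ", path)
  }
  vals <- suppressWarnings(lapply(cells, as.numeric))
  for (ri in seq_along(vals)) {
    bad <- which(is.na(vals[[ri]]) & !(toupper(trimws(cells[[ri]])) %in% c("NA", "NAN")))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row %d, column %d: '%s'",
                   path, ri, bad[1L], cells[[ri]][bad[1L]]))
  }
  A <- do.call(rbind, vals)
  if (nrow(A) != ncol(A))
    stop(sprintf("matrix in %s is not square: %d x %d", path, nrow(A), ncol(A)))
  if (!is.null(labels)) {
    if (length(labels) != ncol(A))
      stop("header length does not match number of columns in ", path)
    colnames(A) <- labels
  }
  A
}

#' @rdname read_connection_matrix
#' @export
write_connection_matrix <- function(A, path, labels = colnames(A), sep = ",") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("'A' must be a square matrix")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels)) writeLines(paste(labels, collapse = sep), con)
  txt <- apply(A, 1L, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = sep))
  writeLines(txt, con)
  invisible(path)
}
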