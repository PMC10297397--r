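test_that("padding embeds a matrix into the next p-power size", {
  A5 <- matrix(1, 5, 5)
  p5 <- pad_matrix(A5, 2)
  expect_equal(dim(p5$values), c(8, 8))
  expect_equal(p5$k, 3)
  expect_equal(p5$values[1:5, 1:5], A5)
  expect_true(all(p5$values[6:8, ] == 0) && all(p5$values[, 6:8] == 0))
  A4 <- matrix(stats::rnorm(16), 4, 4)
  expect_equal(pad_matrix(A4, 2)$values, A4)
  expect_equal(pad_matrix(matrix(0, 64, 64), 2)$k, 6)
  expect_error(pad_matrix(matrix(1, 3, 4), 2), "square")
})

test_that("reduction-map blocks partition the matrix into p^2r ball pairs", {
  b0 <- block_partition(k = 2, r = 0, p = 2)
  expect_length(b0, 1)
  expect_equal(nrow(b0[[1]]), 16)
  b2 <- block_partition(k = 2, r = 2, p = 2)
  expect_length(b2, 16)
  expect_true(all(vapply(b2, nrow, 0L) == 1L))
  b1 <- block_partition(k = 2, r = 1, p = 2)
  expect_length(b1, 4)
  expect_true(all(vapply(b1, nrow, 0L) == 4L))
  blk <- b1[["0,1"]]
  expect_setequal(paste(blk[, "i"], blk[, "j"]),
                  c("0 1", "0 3", "2 1", "2 3"))
  # partition property: every entry in exactly one block
  all_pairs <- do.call(rbind, b1)
  expect_equal(nrow(all_pairs), 16)
  expect_equal(anyDuplicated(paste(all_pairs[, 1], all_pairs[, 2])), 0)
})

test_that("blocks at resolution r+1 refine blocks at resolution r", {
  p <- 2; k <- 3
  for (r in 0:(k - 1)) {
    coarse <- block_partition(k, r, p)
    fine <- block_partition(k, r + 1, p)
    pr <- p^r
    for (nm in names(fine)) {
      ab <- as.integer(strsplit(nm, ",")[[1]])
      parent <- paste(ab[1] %% pr, ab[2] %% pr, sep = ",")
      fp <- paste(fine[[nm]][, 1], fine[[nm]][, 2])
      cp <- paste(coarse[[parent]][, 1], coarse[[parent]][, 2])
      expect_true(all(fp %in% cp))
    }
  }
})

test_that("local circulant averaging reproduces the worked 2x2 example", {
  A <- matrix(c(1, 5, 3, 7), 2, 2)       # rows: (1 3), (5 7)
  K <- local_circulant_average(A, p = 2, k = 1, r = 0)
  expect_equal(K$values, matrix(4, 2, 2))
})

test_that("averaging is an idempotent, sum-preserving projection", {
  set.seed(21)
  p <- 2; k <- 3; n <- p^k
  A <- matrix(stats::rnorm(n * n), n, n)
  for (r in 0:k) {
    K <- local_circulant_average(A, p, k, r)
    expect_equal(sum(K$values), sum(A))
    K2 <- local_circulant_average(K$values, p, k, r)
    expect_equal(K2$values, K$values, tolerance = 1e-12)
  }
  expect_identical(local_circulant_average(A, p, k, k)$values, A)
})

test_that("a circulant matrix is a fixed point at every resolution", {
  g <- padic_grid(2, 3)
  w <- stats::rnorm(8)
  C <- circulant_matrix(w, g)
  for (r in 0:3)
    expect_equal(local_circulant_average(C, 2, 3, r)$values, C,
                 tolerance = 1e-12)
})

test_that("within blocks the kernel depends only on the group difference", {
  set.seed(22)
  p <- 3; k <- 2; n <- p^k
  A <- matrix(stats::rnorm(n * n), n, n)
  for (r in 0:k) {
    K <- local_circulant_average(A, p, k, r)$values
    pr <- p^r
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      for (i2 in 0:(n - 1)) for (j2 in 0:(n - 1)) {
        same_block <- (i %% pr == i2 %% pr) && (j %% pr == j2 %% pr)
        same_diff <- ((i - j) %% n) == ((i2 - j2) %% n)
        if (same_block && same_diff)
          expect_equal(K[i + 1, j + 1], K[i2 + 1, j2 + 1])
      }
    }
  }
})

test_that("mean-square approximation error is nonincreasing in resolution", {
  set.seed(23)
  for (rep_i in 1:5) {
    A <- matrix(stats::rnorm(64), 8, 8)
    ms <- vapply(0:3, function(r)
      approximation_error(A, local_circulant_average(A, 2, 3, r))$mean_square,
      0)
    expect_true(all(diff(ms) <= 1e-12))
    expect_equal(ms[4], 0)
  }
  A6 <- synthetic_hierarchical_matrix(2, 6, decay = 1, noise_sd = 0.3,
                                      seed = 99)
  ms6 <- vapply(0:6, function(r)
    approximation_error(A6, local_circulant_average(A6, 2, 6, r))$mean_square,
    0)
  expect_true(all(diff(ms6) <= 1e-12))
  expect_equal(ms6[7], 0)
})

test_that("synthetic hierarchical matrices decay with tree distance", {
  A <- synthetic_hierarchical_matrix(2, 4, decay = 1, noise_sd = 0, seed = 1)
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0))
  # noise-free: circulant, so exactly reproduced at every resolution
  for (r in c(0, 2, 4))
    expect_equal(local_circulant_average(A, 2, 4, r)$values, A,
                 tolerance = 1e-12)
  # monotone: sibling leaves couple more strongly than distant ones
  g <- padic_grid(2, 4)
  d <- ultrametric_distance(0, g$indices[-1], g)
  w <- A[1, -1]
  expect_true(all(diff(w[order(d)]) <= 1e-12))
  # determinism and noise effect
  B1 <- synthetic_hierarchical_matrix(3, 2, 0.8, 0.2, seed = 5)
  B2 <- synthetic_hierarchical_matrix(3, 2, 0.8, 0.2, seed = 5)
  expect_identical(B1, B2)
  expect_false(identical(B1, synthetic_hierarchical_matrix(3, 2, 0.8, 0.2,
                                                           seed = 6)))
  expect_true(all(B1 >= 0) && all(diag(B1) == 0))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(31); a <- stats::rnorm(1)
  set.seed(31)
  invisible(synthetic_hierarchical_matrix(2, 3, 1, 0.5, seed = 77))
  expect_identical(stats::rnorm(1), a)
})

test_that("matrix text round trip is lossless and errors are located", {
  set.seed(24)
  A <- matrix(stats::rnorm(64), 8, 8)
  f <- tempfile(fileext = ".csv")
  write_connection_matrix(A, f)
  B <- read_connection_matrix(f)
  expect_lt(max(abs(A - B)), 1e-12)
  # labels preserved
  colnames(A) <- paste0("n", 1:8)
  write_connection_matrix(A, f)
  expect_identical(colnames(read_connection_matrix(f)), paste0("n", 1:8))
  # non-square input
  writeLines(c("1,2,3,4", "5,6,7,8"), f)
  expect_error(read_connection_matrix(f), "not square")
  # ragged rows
  writeLines(c("1,2", "3"), f)
  expect_error(read_connection_matrix(f), "ragged")
  # non-numeric cell with location
  writeLines(c("1,2", "3,x"), f)
  expect_error(read_connection_matrix(f), "row 2, column 2")
})
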