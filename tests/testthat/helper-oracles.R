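# Independent brute-force oracles used across the test files.

# Direct double-sum group convolution: p^(-l) * sum_i w_{(k-i) mod n} phi_i.
convolve_direct <- function(w, phi, grid) {
  n <- grid$size
  out <- numeric(n)
  for (k in 0:(n - 1L)) {
    s <- 0
    for (i in 0:(n - 1L)) s <- s + w[((k - i) %% n) + 1L] * phi[i + 1L]
    out[k + 1L] <- s / n
  }
  out
}

# Base conversion oracle (independent of padic_digits).
digits_oracle <- function(i, p, l) {
  out <- integer(l)
  for (j in seq_len(l)) {
    out[j] <- i %% p
    i <- i %/% p
  }
  out
}

# Exhaustive ball membership on the grid.
ball_members <- function(center, r, grid) {
  grid$indices[(grid$indices - center) %% (grid$p^r) == 0]
}

# Shared network used by the reference experiments (radial kernels and
# sigmoids of the pulse/hysteresis simulations) on an arbitrary grid.
sim1_model <- function(grid, r_E = 1, r_I = 1, h_E = stim_zero(),
                       h_I = stim_zero(), tau = 10) {
  wc_model(grid, tau = tau, r_E = r_E, r_I = r_I,
           w_EE = radial_kernel(1.5, 4), w_EI = radial_kernel(1.35, 6),
           w_IE = radial_kernel(1.35, 6), w_II = radial_kernel(1.8, 3),
           S_E = wc_sigmoid(2.75, 9), S_I = wc_sigmoid(0.3, 17),
           h_E = h_E, h_I = h_I)
}

# The four-indicator test field used as the package's heat-map worked
# example: level-4 dyadic grid, +1 on the singleton balls at 0, 1, 7 and
# -1 on the singleton ball at 2.
four_indicator_field <- function() {
  g <- padic_grid(2, 4)
  phi <- ball_indicator(g$indices, 0, 4, g) -
         ball_indicator(g$indices, 2, 4, g) +
         ball_indicator(g$indices, 1, 4, g) +
         ball_indicator(g$indices, 7, 4, g)
  list(grid = g, phi = phi)
}

zero_matrix_model <- function(grid, tau = 10, r_E = 0, r_I = 0,
                              S_E = wc_sigmoid(2.75, 9),
                              S_I = wc_sigmoid(0.3, 17),
                              h_E = stim_zero(), h_I = stim_zero()) {
  Z <- matrix(0, grid$size, grid$size)
  wc_model(grid, tau = tau, r_E = r_E, r_I = r_I,
           w_EE = Z, w_EI = Z, w_IE = Z, w_II = Z,
           S_E = S_E, S_I = S_I, h_E = h_E, h_I = h_I)
}
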