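test_that("presets carry the reference parameter set", {
  cfg <- wc_preset("sim1_pulse")
  expect_equal(cfg$p, 3); expect_equal(cfg$l, 6)
  expect_equal(cfg$tau, 10)
  expect_equal(cfg$r_E, 1); expect_equal(cfg$r_I, 1)
  expect_equal(cfg$kernels,
               list(b_EE = 1.5, sigma_EE = 4, b_II = 1.8, sigma_II = 3,
                    b_IE = 1.35, sigma_IE = 6, b_EI = 1.35, sigma_EI = 6))
  expect_equal(cfg$sigmoids,
               list(v_E = 2.75, theta_E = 9, v_I = 0.3, theta_I = 17))
  expect_equal(cfg$time, list(t_end = 100, dt = 0.05))
  expect_equal(cfg$stimulus$amplitude, 3.7)
  expect_equal(cfg$stimulus$delta, 5)
  expect_equal(wc_preset("sim1_maintained")$time$t_end, 200)
  expect_equal(wc_preset("sim1_maintained")$stimulus$delta, 100)
  expect_equal(wc_preset("sim1_inhib")$stimulus$Q, -30)
  expect_equal(wc_preset("hysteresis_open")$time$t_end, 60)
  cr <- wc_preset("connectome_run")
  expect_equal(cr$p, 2)
  expect_equal(cr$time$t_end, 150)
  expect_equal(cr$stimulus$amplitude, 3.5)
  expect_error(wc_preset("nope"))
})

test_that("preset overrides merge recursively", {
  cfg <- wc_preset("sim1_pulse", l = 3, time = list(t_end = 10))
  expect_equal(cfg$l, 3)
  expect_equal(cfg$time$t_end, 10)
  expect_equal(cfg$time$dt, 0.05)        # untouched sibling survives
})

test_that("a zero-stimulus run from rest is identically zero", {
  ex <- run_experiment(wc_preset("custom", l = 2, time = list(t_end = 2)))
  expect_true(all(ex$trajectory$E == 0) && all(ex$trajectory$I == 0))
  expect_equal(ex$metrics$final_spatial_peaks_E, 0L)
})

test_that("connectome run at r = k on a noise-free matrix equals the
           equivalent convolutional coupling", {
  cfg <- wc_preset("connectome_run", l = 3,
                   connectome = list(k = 3, r = 3, noise_sd = 0),
                   time = list(t_end = 5))
  ex_mat <- run_experiment(cfg)
  # noise-free synthetic matrix is circulant: column 0 is its kernel vector
  g <- padic_grid(2, 3)
  A <- synthetic_hierarchical_matrix(2, 3, decay = 1, noise_sd = 0)
  m_conv <- wc_model(g, 10, 1, 1,
                     w_EE = A[, 1], w_EI = radial_kernel(1.35, 6),
                     w_IE = radial_kernel(1.35, 6), w_II = radial_kernel(1.8, 3),
                     S_E = wc_sigmoid(2.75, 9), S_I = wc_sigmoid(0.3, 17),
                     h_E = stim_ball_constant(3.5, 1, 2),
                     h_I = stim_ball_constant(-30, 0, 0))
  tr_conv <- wc_integrate(m_conv, t_end = 5, dt = 0.05)
  expect_lt(max(abs(ex_mat$trajectory$E - tr_conv$E)), 1e-10)
  expect_lt(max(abs(ex_mat$trajectory$I - tr_conv$I)), 1e-10)
})

test_that("heat-map export writes the four-indicator example faithfully", {
  ex <- four_indicator_field()
  tr <- wc_trajectory(times = 0, E = ex$phi, grid = ex$grid)
  f <- tempfile()
  H <- export_heatmap(tr, f, which = "E", ordering = "integer")
  expect_equal(dim(H), c(16L, 1L))       # single time -> one column
  vals <- as.numeric(readLines(f))
  expect_equal(vals[c(0, 1, 7) + 1], c(1, 1, 1))
  expect_equal(vals[2 + 1], -1)
  expect_true(all(vals[-(c(0, 1, 2, 7) + 1)] == 0))
  meta <- readLines(paste0(f, ".meta"))
  expect_true(any(grepl("^p\t2$", meta)) && any(grepl("^l\t4$", meta)))
  # Monna ordering only permutes rows
  f2 <- tempfile()
  H2 <- export_heatmap(tr, f2, which = "E", ordering = "monna")
  ord <- tree_order(ex$grid)
  expect_equal(as.numeric(H2), ex$phi[ord + 1])
  expect_setequal(as.numeric(H2), as.numeric(H))
})

test_that("heat-map text output is byte-reproducible", {
  g <- padic_grid(2, 3)
  m <- sim1_model(g, h_E = stim_ball_pulse(3.7, 1, 1, 2))
  tr <- wc_integrate(m, t_end = 2, dt = 0.1)
  f1 <- tempfile(); f2 <- tempfile()
  export_heatmap(tr, f1); export_heatmap(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("time-major trajectory export carries the time column", {
  g <- padic_grid(2, 2)
  tr <- wc_integrate(zero_matrix_model(g), E0 = rep(1, 4), t_end = 1, dt = 0.5)
  f <- tempfile()
  export_trajectory(tr, f)
  rows <- strsplit(readLines(f), "\t")
  expect_equal(length(rows), 3L)         # t = 0, 0.5, 1
  expect_equal(vapply(rows, function(r) as.numeric(r[1]), 0), c(0, 0.5, 1))
  expect_equal(length(rows[[1]]), 1L + 4L)
})

test_that("spatial peak counting matches the bump examples", {
  g <- padic_grid(2, 3)
  expect_equal(count_spatial_peaks(c(0, 1, 3, 1, 0.2, 0, 0, 0), g, "integer"), 1L)
  expect_equal(count_spatial_peaks(c(0, 2, 0, 0, 0, 2, 0, 0), g, "integer"), 2L)
  # endpoint strictly greater than its neighbor counts
  expect_equal(count_spatial_peaks(c(3, 1, 0, 0, 0, 0, 0, 2), g, "integer"), 2L)
  # sub-threshold wiggles (below 10% of max) are ignored
  expect_equal(count_spatial_peaks(c(0, 10, 0, 0.5, 0, 0.5, 0, 0), g, "integer"), 1L)
  # nonpositive fields have no peaks
  expect_equal(count_spatial_peaks(rep(0, 8), g, "integer"), 0L)
  # single Gaussian bump in the Monna coordinate
  g6 <- padic_grid(3, 6)
  f <- exp(-(30 * (0.5 - monna_map(g6$indices, g6)))^2)
  expect_equal(count_spatial_peaks(f, g6, "monna"), 1L)
})

test_that("temporal oscillation counting ignores endpoints", {
  g <- padic_grid(2, 2)
  t_dec <- seq(0, 5, by = 0.1)
  tr_dec <- wc_trajectory(t_dec, E = matrix(exp(-t_dec), ncol = 1) %*%
                            rep(1, 4), grid = g)
  expect_equal(count_temporal_oscillations(tr_dec, 0), 0L)
  t_sin <- seq(0, 6 * pi, length.out = 400)
  tr_sin <- wc_trajectory(t_sin, E = matrix(sin(t_sin), ncol = 1) %*%
                            rep(1, 4), grid = g)
  expect_equal(count_temporal_oscillations(tr_sin, 2), 3L)
})

test_that("yaml config files override presets", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("name: sim1_pulse", "l: 2", "time:", "  t_end: 1"), f)
  cfg <- read_experiment_config(f)
  expect_s3_class(cfg, "wc_config")
  expect_equal(cfg$name, "sim1_pulse")
  expect_equal(cfg$l, 2)
  expect_equal(cfg$time$t_end, 1)
  expect_equal(cfg$time$dt, 0.05)
})
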