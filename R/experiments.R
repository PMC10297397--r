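#' Experiment presets
#'
#' Ready-made configurations reproducing the package's reference
#' numerical experiments.  All pulse/hysteresis presets share the same
#' network: \eqn{p = 3}, \eqn{l = 6}, \eqn{\tau = 10},
#' \eqn{r_E = r_I = 1}, radial kernels with
#' \eqn{b_{EE} = 1.5, \sigma_{EE} = 4}, \eqn{b_{II} = 1.8, \sigma_{II} = 3},
#' \eqn{b_{IE} = b_{EI} = 1.35, \sigma_{IE} = \sigma_{EI} = 6}, sigmoids
#' \eqn{v_E = 2.75, \theta_E = 9} and \eqn{v_I = 0.3, \theta_I = 17},
#' step \eqn{dt = 0.05}, and rest initial conditions.
#'
#' * `sim1_pulse`: brief localized excitatory pulse (amplitude 3.7 on
#'   the ball \eqn{4 + p^2 Z_p}, duration \eqn{\delta = 5}, \eqn{Q = 0}),
#'   run to \eqn{t = 100}.
#' * `sim1_maintained`: same pulse maintained (\eqn{\delta = 100}), run
#'   to \eqn{t = 200}; the response is a pulse train.
#' * `sim1_inhib`: maintained pulse plus a spatially uniform inhibitory
#'   input at level \eqn{Q = -30}, run to \eqn{t = 100}.
#' * `hysteresis_open` / `hysteresis_return`: the binocular two-peak
#'   stimulus ([stim_hysteresis()]) on the excitatory population,
#'   \eqn{h_I \equiv 0}, run to \eqn{t = 60}.
#' * `connectome_run`: \eqn{p = 2}, \eqn{l = 6}; the E-to-E coupling is
#'   the resolution-`r` kernel matrix of a connection matrix (an
#'   external file, or the synthetic hierarchical generator), the other
#'   couplings as above; constant stimuli \eqn{h_E = 3.5} on the ball
#'   \eqn{1 + p^2 Z_p} and \eqn{h_I \equiv -30}; run to \eqn{t = 150}.
#' * `custom`: the shared network with zero stimulus; override fields as
#'   needed.
#'
#' @param name preset name.
#' @param ... named overrides, merged recursively into the preset (e.g.
#'   `time = list(t_end = 10)`, `connectome = list(r = 5)`).
#' @return A `wc_config` list with components `name`, `p`, `l`, `tau`,
#'   `r_E`, `r_I`, `kernels`, `sigmoids`, `stimulus`, `time`,
#'   `connectome`, `ordering`.
#' @export
wc_preset <- function(name = c("sim1_pulse", "sim1_maintained", "sim1_inhib",
                               "hysteresis_open", "hysteresis_return",
                               "connectome_run", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name, p = 3L, l = 6L, tau = 10, r_E = 1, r_I = 1,
    kernels = list(b_EE = 1.5, sigma_EE = 4, b_II = 1.8, sigma_II = 3,
                   b_IE = 1.35, sigma_IE = 6, b_EI = 1.35, sigma_EI = 6),
    sigmoids = list(v_E = 2.75, theta_E = 9, v_I = 0.3, theta_I = 17),
    stimulus = list(kind = "none", amplitude = 3.7, center = 4L,
                    radius_exponent = 2L, delta = 5, Q = 0, mode = "open"),
    time = list(t_end = 100, dt = 0.05),
    connectome = list(matrix_path = NULL, k = 6L, r = 3L, decay = 1,
                      noise_sd = 0.1, seed = 1L, amplitude = 3),
    ordering = "monna")
  cfg <- switch(name,
    sim1_pulse = base,
    sim1_maintained = {
      base$stimulus$delta <- 100; base$time$t_end <- 200; base
    },
    sim1_inhib = {
      base$stimulus$delta <- 100; base$stimulus$Q <- -30
      base$time$t_end <- 100; base
    },
    hysteresis_open = ,
    hysteresis_return = {
      base$stimulus$kind <- "hysteresis"
      base$stimulus$mode <- sub("hysteresis_", "", name)
      base$time$t_end <- 60; base
    },
    connectome_run = {
      base$p <- 2L; base$l <- 6L
      base$stimulus$kind <- "constant"
      base$stimulus$amplitude <- 3.5
      base$stimulus$center <- 1L
      base$stimulus$Q <- -30
      base$time$t_end <- 150; base
    },
    custom = { base$time$t_end <- 10; base })
  if (name %in% c("sim1_pulse", "sim1_maintained", "sim1_inhib"))
    cfg$stimulus$kind <- "pulse"
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "wc_config"
  cfg
}

#' Read an experiment configuration file
#'
#' Reads a YAML configuration.  The file must contain a `name` entry
#' naming a preset (or `custom`); all other entries override the preset
#' fields, with the same nesting as [wc_preset()].
#'
#' @param path YAML file path.
#' @return A `wc_config` list.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name)) stop("config file must contain a 'name' entry")
  nm <- raw$name
  raw$name <- NULL
  do.call(wc_preset, c(list(name = nm), raw))
}

#' Build the model described by a configuration
#'
#' @param config a `wc_config` from [wc_preset()] or
#'   [read_experiment_config()].
#' @return List with `grid` and `model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "wc_config"))
  grid <- padic_grid(config$p, config$l)
  kr <- config$kernels
  w_EE <- radial_kernel(kr$b_EE, kr$sigma_EE)
  w_II <- radial_kernel(kr$b_II, kr$sigma_II)
  w_IE <- radial_kernel(kr$b_IE, kr$sigma_IE)
  w_EI <- radial_kernel(kr$b_EI, kr$sigma_EI)
  st <- config$stimulus
  h_E <- stim_zero(); h_I <- stim_zero()
  if (st$kind == "pulse") {
    h_E <- stim_ball_pulse(st$amplitude, st$center, st$radius_exponent,
                           st$delta)
    if (st$Q != 0)
      h_I <- stim_ball_pulse(st$Q, st$center, 0L, st$delta)
  } else if (st$kind == "hysteresis") {
    h_E <- stim_hysteresis(st$mode)
  } else if (st$kind == "constant") {
    h_E <- stim_ball_constant(st$amplitude, st$center, st$radius_exponent)
    if (st$Q != 0) h_I <- stim_ball_constant(st$Q, 0L, 0L)
  }
  if (config$name == "connectome_run" || !is.null(config$connectome$use)) {
    cn <- config$connectome
    A <- if (!is.null(cn$matrix_path)) read_connection_matrix(cn$matrix_path)
         else synthetic_hierarchical_matrix(config$p, cn$k, cn$decay,
                                            cn$noise_sd, cn$seed, cn$amplitude)
    pad <- pad_matrix(unname(A), config$p)
    if (pad$k > config$l)
      stop("padded connection matrix exceeds the grid: p^k > p^l")
    if (pad$k < config$l)
      stop("connection matrix level k must match the grid level l")
    if (cn$r > pad$k) stop("resolution r must satisfy r <= k")
    w_EE <- local_circulant_average(pad$values, config$p, pad$k, cn$r)
  }
  model <- wc_model(grid, config$tau, config$r_E, config$r_I,
                    w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
                    S_E = wc_sigmoid(config$sigmoids$v_E, config$sigmoids$theta_E),
                    S_I = wc_sigmoid(config$sigmoids$v_I, config$sigmoids$theta_I),
                    h_E = h_E, h_I = h_I)
  list(grid = grid, model = model)
}

#' Run a configured experiment
#'
#' Integrates the configured model from rest (unless initial fields are
#' supplied), and summarizes the response: spatial peak count of the
#' final excitatory field in the configured ordering, temporal
#' oscillation count at the stimulated site, activity extrema, and --
#' when both refractory coefficients are zero -- the a-priori bound
#' check \eqn{\sup_t \max_x |E| \le \|E_0\|_\infty + \tau \|S_E\|_\infty}.
#'
#' @param config a `wc_config`.
#' @param E0,I0 optional initial fields (default rest).
#' @param method integration scheme, `"rk4"` or `"euler"`.
#' @param verbose log run parameters to stderr.
#' @return List of class `wc_experiment` with `config`, `trajectory`,
#'   and `metrics`.
#' @export
run_experiment <- function(config, E0 = NULL, I0 = NULL,
                           method = "rk4", verbose = FALSE) {
  stopifnot(inherits(config, "wc_config"))
  built <- build_model(config)
  if (verbose)
    message(sprintf(
      "[padicwc %s] preset %s: p=%d l=%d tau=%g rE=%g rI=%g dt=%g t_end=%g",
      as.character(utils::packageVersion("padicwc")), config$name,
      config$p, config$l, config$tau, config$r_E, config$r_I,
      config$time$dt, config$time$t_end))
  traj <- wc_integrate(built$model, E0 = E0, I0 = I0,
                       t_end = config$time$t_end, dt = config$time$dt,
                       method = method)
  final_E <- traj$E[nrow(traj$E), ]
  site <- config$stimulus$center
  if (is.null(site) || config$stimulus$kind == "hysteresis")
    site <- which.max(colSums(abs(traj$E))) - 1L
  metrics <- list(
    final_spatial_peaks_E = count_spatial_peaks(final_E, built$grid,
                                                config$ordering),
    temporal_oscillations = count_temporal_oscillations(traj, site),
    readout_site = site,
    max_abs_E = max(abs(traj$E)), max_abs_I = max(abs(traj$I)),
    min_E = min(traj$E), max_E = max(traj$E))
  if (config$r_E == 0 && config$r_I == 0) {
    bE <- sigmoid_bounds(built$model$S_E)$sup_norm
    bI <- sigmoid_bounds(built$model$S_I)$sup_norm
    e0 <- if (is.null(E0)) 0 else max(abs(E0))
    i0 <- if (is.null(I0)) 0 else max(abs(I0))
    metrics$bound_E <- e0 + config$tau * bE
    metrics$bound_I <- i0 + config$tau * bI
    metrics$bound_satisfied <- (metrics$max_abs_E <= metrics$bound_E + 1e-6) &&
                               (metrics$max_abs_I <= metrics$bound_I + 1e-6)
  }
  structure(list(config = config, trajectory = traj, metrics = metrics),
            class = "wc_experiment")
}

#' @export
print.wc_experiment <- function(x, ...) {
  cat("experiment:", x$config$name, "\n")
  print(x$trajectory)
  cat(sprintf("  final spatial peaks (E): %d; temporal maxima at site %d: %d\n",
              x$metrics$final_spatial_peaks_E, x$metrics$readout_site,
              x$metrics$temporal_oscillations))
  if (!is.null(x$metrics$bound_satisfied))
    cat(sprintf("  a-priori bound %s (max|E| = %.4g <= %.4g)\n",
                if (x$metrics$bound_satisfied) "satisfied" else "VIOLATED",
                x$metrics$max_abs_E, x$metrics$bound_E))
  invisible(x)
}

#' Assemble a trajectory object from raw arrays
#'
#' Mainly useful for exporting static fields (a one-time-point
#' trajectory) through [export_heatmap()].
#'
#' @param times numeric vector of time points.
#' @param E,I numeric matrices, `length(times) x grid$size`; a vector is
#'   treated as a single time point.  `I` defaults to zeros.
#' @param grid a [padic_grid()].
#' @return A `wc_trajectory`.
#' @export
wc_trajectory <- function(times, E, I = NULL, grid) {
  if (is.vector(E)) E <- matrix(E, nrow = 1L)
  if (is.null(I)) I <- matrix(0, nrow(E), ncol(E))
  if (is.vector(I)) I <- matrix(I, nrow = 1L)
  stopifnot(inherits(grid, "padic_grid"),
            nrow(E) == length(times), ncol(E) == grid$size,
            all(dim(I) == dim(E)), all(is.finite(E)), all(is.finite(I)))
  dt <- if (length(times) > 1L) times[2L] - times[1L] else NA_real_
  structure(list(times = times, E = unname(E), I = unname(I), grid = grid,
                 dt = dt, method = "assembled"),
            class = "wc_trajectory")
}

heat_matrix <- function(traj, which, ordering) {
  vals <- traj[[which]]
  ord <- switch(ordering,
                monna = tree_order(traj$grid),
                integer = traj$grid$indices,
                stop("'ordering' must be 'monna' or 'integer'"))
  t(vals)[ord + 1L, , drop = FALSE]   # rows = sites (ordered), cols = times
}

#' Export a trajectory as a heat-map matrix
#'
#' Writes the space-by-time matrix (rows = sites in the chosen ordering,
#' columns = time points) as tab-delimited text at 15 significant
#' digits, plus a companion `<path>.meta` file recording `p`, `l`,
#' `dt`, the ordering, the population and the site order.  Output is
#' byte-reproducible.  If `image = TRUE` (requires the `png` package) a
#' grayscale raster with the same row order, mapped linearly from
#' `[min, max]` to black..white, is written next to it as `<path>.png`.
#'
#' @param traj a `wc_trajectory`.
#' @param path output path for the text matrix.
#' @param which `"E"` or `"I"`.
#' @param ordering `"monna"` (tree order, balls contiguous; default) or
#'   `"integer"`.
#' @param image also write a PNG raster.
#' @return Invisibly, the exported matrix.
#' @export
export_heatmap <- function(traj, path, which = c("E", "I"),
                           ordering = c("monna", "integer"), image = FALSE) {
  stopifnot(inherits(traj, "wc_trajectory"))
  which <- match.arg(which)
  ordering <- match.arg(ordering)
  H <- heat_matrix(traj, which, ordering)
  ord <- switch(ordering, monna = tree_order(traj$grid),
                integer = traj$grid$indices)
  con <- file(path, "w")
  writeLines(apply(H, 1L, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = "\t")), con)
  close(con)
  meta <- c(sprintf("p\t%d", traj$grid$p),
            sprintf("l\t%d", traj$grid$l),
            sprintf("dt\t%s", formatC(traj$dt, digits = 15, format = "g")),
            sprintf("ordering\t%s", ordering),
            sprintf("population\t%s", which),
            sprintf("sites\t%s", paste(ord, collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
  if (image) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for image output")
    rng <- range(H)
    img <- if (diff(rng) > 0) (H - rng[1L]) / diff(rng)
           else matrix(0, nrow(H), ncol(H))
    png::writePNG(img, paste0(path, ".png"))
  }
  invisible(H)
}

#' Export a trajectory as time-major delimited text
#'
#' One row per time point (first column the time), remaining columns
#' the sites in the chosen ordering; companion `<path>.meta` as in
#' [export_heatmap()].
#'
#' @inheritParams export_heatmap
#' @return Invisibly, `path`.
#' @export
export_trajectory <- function(traj, path, which = c("E", "I"),
                              ordering = c("integer", "monna")) {
  stopifnot(inherits(traj, "wc_trajectory"))
  which <- match.arg(which)
  ordering <- match.arg(ordering)
  H <- heat_matrix(traj, which, ordering)  # sites x times
  M <- cbind(traj$times, t(H))
  con <- file(path, "w")
  writeLines(apply(M, 1L, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = "\t")), con)
  close(con)
  ord <- switch(ordering, monna = tree_order(traj$grid),
                integer = traj$grid$indices)
  writeLines(c(sprintf("p\t%d", traj$grid$p), sprintf("l\t%d", traj$grid$l),
               sprintf("dt\t%s", formatC(traj$dt, digits = 15, format = "g")),
               sprintf("ordering\t%s", ordering),
               sprintf("population\t%s", which),
               sprintf("sites\t%s", paste(ord, collapse = ","))),
             paste0(path, ".meta"))
  invisible(path)
}

# Local maxima of a sequence, strict with respect to the nearest
# *distinct* neighboring values: consecutive equal values (a plateau)
# are collapsed to one candidate, so a flat-topped bump counts once.
# Values at or below threshold_frac * max are ignored.
count_peaks_seq <- function(x, include_endpoints, threshold_frac = 0.1) {
  n <- length(x)
  if (n < 3L) stop("sequence must have length >= 3")
  mx <- max(x)
  if (mx <= 0) return(0L)
  thr <- threshold_frac * mx
  runs <- rle(x)$values
  k <- length(runs)
  if (k < 2L) return(0L)
  count <- 0L
  for (i in seq_len(k)) {
    if (runs[i] <= thr) next
    left_ok <- if (i == 1L) include_endpoints else runs[i] > runs[i - 1L]
    right_ok <- if (i == k) include_endpoints else runs[i] > runs[i + 1L]
    if (left_ok && right_ok) count <- count + 1L
  }
  count
}

#' Count spatial peaks of a field
#'
#' Number of strict local maxima of the field arranged in the given
#' ordering, ignoring values at or below 10% of the field maximum;
#' an endpoint counts if strictly greater than its single neighbor.
#' Runs of equal consecutive values are collapsed first, so a bump that
#' is constant on a ball (as step-function fields are) counts as one
#' peak.  Operationalizes the "single pulse" vs "twin pulses" readout
#' of the hysteresis experiments.
#'
#' @param field numeric vector of length `grid$size` (length `>= 3`).
#' @param grid a [padic_grid()].
#' @param ordering `"monna"` or `"integer"`.
#' @return Integer peak count.
#' @export
count_spatial_peaks <- function(field, grid, ordering = c("monna", "integer")) {
  ordering <- match.arg(ordering)
  if (length(field) != grid$size) stop("'field' must have length p^l")
  ord <- switch(ordering, monna = tree_order(grid), integer = grid$indices)
  count_peaks_seq(field[ord + 1L], include_endpoints = TRUE)
}

#' Count temporal oscillations at a site
#'
#' Number of strict interior local maxima of \eqn{E(\mathrm{site}, t)}
#' over the trajectory, ignoring values at or below 10% of the temporal
#' maximum.  A monotone response therefore counts 0; a pulse train
#' counts one per pulse.
#'
#' @param traj a `wc_trajectory`.
#' @param site grid index (0-based).
#' @param which `"E"` or `"I"`.
#' @return Integer count.
#' @export
count_temporal_oscillations <- function(traj, site, which = c("E", "I")) {
  stopifnot(inherits(traj, "wc_trajectory"))
  which <- match.arg(which)
  site <- check_index(site, traj$grid)
  count_peaks_seq(traj[[which]][, site + 1L], include_endpoints = FALSE)
}
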