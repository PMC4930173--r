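#' Hexagonal-lattice initial cluster
#'
#' Places `N` cells on a unit-spacing triangular lattice: closed hexagonal
#' shells for N in 1, 7, 19, 37, 61, 91, 127, and otherwise the `N` lattice
#' sites closest to the lattice origin (ties broken by angle,
#' deterministically). The cluster is centred on its centroid and rotated
#' as a whole by `angle` (or a uniform random angle when `angle = NULL`),
#' so each trajectory can start at a random orientation while the gradient
#' stays fixed.
#'
#' @param N Number of cells (>= 1).
#' @param angle Rotation angle in radians; `NULL` draws one uniformly from
#'   the current RNG stream.
#' @return An N x 2 matrix of positions.
#' @examples
#' init_hexagonal_cluster(7, angle = 0)
#' @export
init_hexagonal_cluster <- function(N, angle = NULL) {
  if (!is.numeric(N) || N < 1) rlang::abort("N must be a positive integer")
  N <- as.integer(N)
  m <- ceiling(sqrt(N)) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  px <- ij$i + ij$j / 2
  py <- ij$j * sqrt(3) / 2
  d <- sqrt(px^2 + py^2)
  ord <- order(round(d, 9), round(atan2(py, px), 9))
  sel <- ord[seq_len(N)]
  pos <- cbind(px[sel], py[sel])
  pos <- sweep(pos, 2, colMeans(pos))
  if (is.null(angle)) angle <- stats::runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pos %*% t(rot)
}

new_sim_state <- function(positions, polarities = NULL, legi = NULL,
                          t = 0) {
  pos <- as_positions(positions)
  n <- nrow(pos)
  if (is.null(polarities)) polarities <- matrix(0, n, 2)
  pol <- as_positions(polarities)
  stopifnot(nrow(pol) == n)
  structure(list(t = t, positions = pos, polarities = pol, legi = legi),
            class = "sim_state")
}

# Default inhibitor initialization: the uniform steady state for the mean
# initial signal over the cluster.
init_legi_state <- function(params, field, pos, t = 0) {
  if (params$response_mode == "minimal") return(NULL)
  r <- params$legi
  s <- signal_at(field, pos, t = t)
  sbar <- mean(s)
  I0 <- rep((r$kI / r$k_mI) * sbar, nrow(pos))
  A0 <- (r$kA / r$k_mA) * s
  R0 <- r$kR * A0 / (r$kR * A0 + r$k_mR * I0)
  list(A = A0, I = I0, R = R0)
}

#' Deterministic polarity rate
#'
#' The drift part of the polarity dynamics for a given state:
#' `-p_i / tau + beta_i q_i + chemotaxis bias`, with the susceptibility
#' `beta_i` from the configured response mode (for the LEGI modes the
#' response is taken at its steady state for the current configuration).
#' Mainly an inspection/testing tool; the integrator applies the same
#' terms internally.
#'
#' @param positions,polarities N x 2 matrices (or data frames with x/y).
#' @param params A [model_params()].
#' @param field A [signal_field()].
#' @param t Time at which to evaluate the signal.
#' @return A tibble with columns `cell`, `dpx`, `dpy`, `beta`.
#' @export
polarity_rate <- function(positions, polarities, params, field, t = 0) {
  pos <- as_positions(positions)
  pol <- as_positions(polarities)
  graph <- contact_graph(pos, cutoff = params$D0)
  s <- signal_at(field, pos, t = t)
  beta <- switch(params$response_mode,
    minimal = susceptibility_minimal(s, params$beta_bar),
    {
      ss <- legi_steady_state(s, graph, params$legi)
      susceptibility_from_response(
        ss$R, params$legi, params$beta_bar,
        mode = if (params$response_mode == "legi_switch") "switch" else "linear",
        lam = params$lam)
    })
  q <- cil_bias(pos, graph)
  if (params$chi > 0) {
    gc <- coattract_gradient(pos, ell = params$ell)
    cb <- chemotaxis_bias(gc, chi = params$chi, g0 = params$g0)
  } else {
    cb <- tibble::tibble(bx = numeric(nrow(pos)), by = numeric(nrow(pos)))
  }
  tibble::tibble(
    cell = seq_len(nrow(pos)),
    dpx = -pol[, 1] / params$tau + beta * q$qx + cb$bx,
    dpy = -pol[, 2] / params$tau + beta * q$qy + cb$by,
    beta = beta)
}

run_core <- function(state, params, field, n_steps, snap_every) {
  pp <- cpp_par(params, field)
  lg <- state$legi
  n <- nrow(state$positions)
  empty <- numeric(0)
  cg_simulate_cpp(state$positions, state$polarities,
                  if (is.null(lg)) empty else lg$I,
                  if (is.null(lg)) empty else lg$A,
                  if (is.null(lg)) empty else lg$R,
                  pp, as.integer(n_steps), as.integer(snap_every),
                  state$t)
}

#' Advance the simulation by one or more Euler-Maruyama steps
#'
#' One explicit Euler-Maruyama step advances positions with the current
#' polarity plus intercellular forces, and polarities with the
#' Ornstein-Uhlenbeck drift, the CIL bias, the co-attraction bias, and a
#' noise increment of standard deviation `sigma * sqrt(2 dt)` per
#' component (the factor 2 matches the polarity noise correlator). The
#' contact graph is recomputed every step. Uses R's RNG stream.
#'
#' @param state A state from [new_sim_state()] or a previous `sim_step()`.
#' @param params A [model_params()].
#' @param field A [signal_field()].
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced state (class `sim_state`).
#' @export
sim_step <- function(state, params, field, n_steps = 1) {
  res <- run_core(state, params, field, n_steps, snap_every = n_steps)
  legi <- if (params$response_mode != "minimal")
    list(A = res$A, I = res$I, R = res$Rfinal) else NULL
  new_sim_state(res$positions, res$polarities, legi = legi,
                t = res$t_final)
}

#' Simulate one cluster trajectory
#'
#' Initializes a hexagonal cluster at a random orientation with zero
#' polarities (and, in LEGI modes, the inhibitor at its uniform steady
#' state for the initial mean signal), then integrates the full stochastic
#' dynamics for `T` time units, recording snapshots every `snapshot_dt`.
#' The result is a deterministic function of `(params, field, N, T, seed)`.
#'
#' @param params A [model_params()].
#' @param field A [signal_field()].
#' @param N Number of cells.
#' @param T Trajectory duration in units of `tau`.
#' @param seed Integer seed for this trajectory.
#' @param snapshot_dt Snapshot cadence (default `0.1`; keep at or below
#'   `0.1 tau` when angular velocities are of interest).
#' @param positions Optional explicit initial positions (disables the
#'   random orientation).
#' @param polarities Optional explicit initial polarities (default zero).
#' @return A `cg_trajectory`: a tibble in long format with columns `t`,
#'   `cell`, `x`, `y`, `px`, `py` (and `R` in LEGI modes), carrying the
#'   parameters, seed and single-pass statistics as attributes.
#' @examples
#' tr <- run_trajectory(model_params(beta_bar = 20), signal_field("uniform"),
#'                      N = 7, T = 2, seed = 1)
#' @export
run_trajectory <- function(params, field, N, T, seed,
                           snapshot_dt = 0.1, positions = NULL,
                           polarities = NULL) {
  stopifnot(T > 0)
  set.seed(seed)
  if (is.null(positions)) positions <- init_hexagonal_cluster(N)
  pos <- as_positions(positions)
  stopifnot(nrow(pos) == N)
  legi <- init_legi_state(params, field, pos)
  state <- new_sim_state(pos, polarities, legi = legi)
  n_steps <- max(1L, round(T / params$dt))
  snap_every <- max(1L, round(snapshot_dt / params$dt))
  res <- run_core(state, params, field, n_steps, snap_every)
  n_frames <- length(res$times)
  out <- tibble::tibble(
    t = rep(res$times, each = N),
    cell = rep(seq_len(N), times = n_frames),
    x = as.vector(t(res$X)),
    y = as.vector(t(res$Y)),
    px = as.vector(t(res$PX)),
    py = as.vector(t(res$PY)))
  if (params$response_mode != "minimal") out$R <- as.vector(t(res$R))
  structure(out,
            class = c("cg_trajectory", class(out)),
            params = params, field = field, seed = seed, N = N,
            stats = list(mean_speed2 = res$mean_speed2,
                         mean_px = res$mean_px, mean_py = res$mean_py))
}

#' Simulate an ensemble of trajectories
#'
#' Runs `n_traj` independent trajectories (one RNG stream each, seeded
#' reproducibly from the master seed) and summarizes each with the standard
#' cluster observables over the measurement `window`.
#'
#' @inheritParams run_trajectory
#' @param n_traj Number of trajectories.
#' @param window Length-2 measurement window in time units; the default
#'   `c(T/4, T)` discards the first quarter as burn-in, matching the
#'   convention used for co-attraction ensembles.
#' @param seed Master seed for the ensemble.
#' @param keep_trajectories If `TRUE`, attach the full trajectory records
#'   as an attribute (memory-heavy; default `FALSE`).
#' @return A tibble with one row per trajectory: `traj`, `seed`, `vx`,
#'   `vy`, `speed`, `omega`, `abs_omega`, `n_fragments`.
#' @export
run_ensemble <- function(params, field, N, T, n_traj, seed,
                         window = NULL, snapshot_dt = 0.1,
                         keep_trajectories = FALSE) {
  if (is.null(window)) window <- c(T / 4, T)
  seeds <- derive_seeds(seed, n_traj)
  records <- vector("list", if (keep_trajectories) n_traj else 0L)
  rows <- purrr::map(seq_len(n_traj), function(k) {
    tr <- run_trajectory(params, field, N, T, seed = seeds[k],
                         snapshot_dt = snapshot_dt)
    if (keep_trajectories) records[[k]] <<- tr
    v <- cluster_velocity(tr, window = window)
    om <- angular_speed(tr, window = window)
    fin <- dplyr::filter(tr, .data$t == max(.data$t))
    frag <- fragmentation_count(cbind(fin$x, fin$y), D0 = params$D0)
    tibble::tibble(traj = k, seed = seeds[k],
                   vx = v$vx, vy = v$vy, speed = sqrt(v$vx^2 + v$vy^2),
                   omega = om$omega, abs_omega = om$abs_omega,
                   n_fragments = frag)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- window
  attr(out, "params") <- params
  attr(out, "field") <- field
  if (keep_trajectories) attr(out, "trajectories") <- records
  out
}
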